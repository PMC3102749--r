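# Observed rearranged chromosome V sizes (Southern blot of PFGE-separated
# chromosomes) and the aCGH-derived size-accounting ingredients: A is the
# region deleted from ChrV (kb), B the summed regions of increased copy
# number joined to ChrV (kb). The wild-type +Ty912 ChrV is 624 kb; the
# predicted rearranged size is 624 - A + B. NA marks the wild-type
# reference lanes where no rearrangement applies.
isolate	observed_kb	deleted_kb	duplicated_kb	duplicated_region
WT_minusTy	617	NA	NA	none
WT_plusTy912	624	NA	NA	none
I8	876	36	261	ChrX-R
I9	815	36	190	ChrXIII-L
I10	768	36	147	ChrIII-R
I11	1086	36	427	ChrXII-R
I12	859	36	214	ChrXIII-L
I13	815	36	165	ChrIII-R
I14	894	36	145	ChrV-R
I15	750	36	128	ChrV-R
I16	805	36	165	ChrIII-R
I17	894	36	261	ChrX-R
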