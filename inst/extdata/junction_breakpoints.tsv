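# Sequenced Ty fusion junctions: the ectopic Ty at the breakpoint, the
# crossover interval(s) in Ty912 coordinates (interval notation: "(" is an
# exclusive lower limit, "[" inclusive, "]" inclusive upper limit;
# multiple intervals are ";"-separated; Nd = not determined), the
# recombining sequence domains, and the junction-recovery method.
isolate	ectopic_ty	breakpoint_intervals	recombination	method
I8	YJRWTy1-2	(2001, 2337]	epsilon_x_epsilon	PCR
I10	unannotated_delta_ChrIII_169203_169540	(4692, 5065];[5585, 5692]	epsilon_x_epsilon;3prime_delta_x_delta	cloning
I11	YLRWTy1-3	(240, 320]	5prime_delta_x_5prime_delta	PCR
I13	unannotated_Ty_at_YCRWdelta10	Nd	epsilon_x_epsilon	PCR
I15	unannotated_partial_delta_ChrV_449317_449626	(44, 162]	5prime_delta_x_delta	PCR
I16	unannotated_Ty_at_YCRWdelta10	Nd	3prime_delta_x_3prime_delta	PCR
I17	YJRWTy1-1	Nd	epsilon_x_epsilon	PCR
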