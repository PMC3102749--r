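# GCR event counts per class from the aCGH survey. The all_genotypes row
# totals the 88 +Ty912 isolates across genotypes. Classes: I terminal
# deletion, II telomere-oriented Ty targets, III centromere-oriented Ty
# targets, IV multiple-Ty targets, V complex GCRs.
genotype	assay	class_I	class_II	class_III	class_IV	class_V
wild_type	minusTy	7	0	0	0	0
all_genotypes	plusTy912	5	53	11	14	5
wild_type	plusTy912	0	7	2	0	1
mre11	plusTy912	0	6	1	1	0
rtt105	plusTy912	0	6	1	0	0
mrc1	plusTy912	0	6	0	1	0
srs2	plusTy912	0	5	1	1	0
mec1_sml1	plusTy912	0	1	1	3	2
rtt109	plusTy912	0	5	0	1	1
spt21	plusTy912	0	2	3	1	1
rad53_sml1	plusTy912	2	2	0	3	0
rtt103	plusTy912	2	4	0	1	0
asf1	plusTy912	0	6	0	1	0
rad27	plusTy912	1	3	2	1	0
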