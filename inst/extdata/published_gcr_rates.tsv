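# Published GCR rates from the fluctuation-assay survey of the -Ty and
# +Ty912 strain backgrounds. Rates are per cell per generation; folds are
# relative to the wild-type rate of the matching assay. censored = TRUE
# marks "<" upper bounds (median mutant count of 0).
grouping	genotype	rate_minusTy	censored_minusTy	fold_minusTy	rate_plusTy912	censored_plusTy912	fold_plusTy912	mutation_class
none	wild_type	2.2e-10	FALSE	1	8.4e-8	FALSE	1	NA
HR	mre11	6.8e-8	FALSE	309	4.2e-6	FALSE	50	IA
HR	rad52	5.1e-9	FALSE	55	1.3e-8	FALSE	0.2	IIIA
HR	rad51	2e-9	FALSE	9	5.9e-7	FALSE	7	IB
HR	rad59	1.6e-9	FALSE	7	6.1e-8	FALSE	0.7	IIA
HR	srs2	2.2e-10	FALSE	1	9.6e-7	FALSE	11	IB
HR	sgs1	2.1e-9	FALSE	10	3.1e-6	FALSE	37	IA
HR	rad51_rad59	1.5e-9	FALSE	8	7.9e-8	FALSE	0.9	IIA
HR	rad52_rad51	4.5e-9	FALSE	20	1.9e-8	FALSE	0.2	IIIA
HR	rad52_rad59	7.9e-9	FALSE	36	6.9e-9	FALSE	0.1	IIIA
HR	rad52_rad51_rad59	4.9e-9	FALSE	22	1.7e-8	FALSE	0.2	IIIA
Replication	rfa1-t33	4.5e-9	FALSE	25	3.5e-7	FALSE	4	IA
Replication	rrm3	1.4e-9	FALSE	6	1.9e-7	FALSE	2	IB
Replication	mms1	1.1e-9	FALSE	5	9.3e-7	FALSE	11	IA
Replication	rad27	5.8e-7	FALSE	2636	1.4e-5	FALSE	166	IA
Replication	cdc9-1	3.3e-7	FALSE	1500	2.5e-5	FALSE	298	IA
Checkpoint	elg1	7.1e-9	FALSE	32	1.1e-6	FALSE	13	IA
Checkpoint	rtt107	5.3e-10	TRUE	2	6.1e-7	FALSE	7	IB
Checkpoint	sml1	4.6e-10	TRUE	2	9.2e-8	FALSE	1	IIB
Checkpoint	mec1_sml1	2.1e-8	FALSE	95	1.1e-6	FALSE	13	IA
Checkpoint	rad53_sml1	1e-8	FALSE	45	1.3e-6	FALSE	12	IA
Checkpoint	dun1	7.3e-8	FALSE	155	5.9e-7	FALSE	7	IA
Checkpoint	chk1	1.3e-8	FALSE	59	2.7e-7	FALSE	3	IA
Checkpoint	tel1	5e-10	TRUE	2	1.4e-7	FALSE	2	IIB
Checkpoint	rad9	2e-9	FALSE	9	8.8e-8	FALSE	1	IIA
Checkpoint	mrc1	7.4e-10	TRUE	3	1.2e-6	FALSE	14	IB
Checkpoint	csm3	6.8e-10	TRUE	3	3.6e-7	FALSE	4	IB
Checkpoint	sic1	2.1e-8	FALSE	95	5.2e-6	FALSE	62	IA
Ty-related	rtt105	3e-8	FALSE	136	4.4e-6	FALSE	52	IA
Ty-related	pmr1	3.4e-10	TRUE	2	1.5e-8	FALSE	0.2	IIIB
MMR	mlh1	6.7e-10	TRUE	3	1.5e-7	FALSE	2	IB
MMR	msh2	5.3e-10	FALSE	2	2.2e-7	FALSE	3	IB
PRR	rad6	1.2e-9	FALSE	6	3e-6	FALSE	36	IB
PRR	rad5	1.6e-9	FALSE	7	8.3e-7	FALSE	10	IA
Chromatin	rlf2	1.2e-7	FALSE	545	1.8e-7	FALSE	2	IA
Chromatin	rtt109	4.8e-10	TRUE	2	2.3e-6	FALSE	27	IB
Chromatin	rtt101	1.6e-9	FALSE	7	8e-7	FALSE	10	IA
Chromatin	asf1	5.3e-9	FALSE	24	1.6e-6	FALSE	19	IA
Chromatin	spt21	5.4e-8	FALSE	245	1.1e-6	FALSE	13	IA
Chromatin	rtt106	1.4e-9	FALSE	6	1.6e-7	FALSE	2	IA
Chromatin	rtt102	5.2e-10	TRUE	2	1e-7	FALSE	1	IIB
Chromatin	sir4	4.8e-10	TRUE	2	9.8e-8	FALSE	1	IIB
Transcription	gal11	3.6e-10	TRUE	2	1.3e-8	FALSE	0.2	IIIB
Transcription	rtt103	5.5e-10	TRUE	3	2e-8	FALSE	0.2	IIIB
Transcription	spt8	5.1e-10	TRUE	2	5.4e-8	FALSE	0.6	IIB
Transcription	spt2	3.2e-10	TRUE	1	2.7e-8	FALSE	0.3	IIB
Transcription	spt4	4.6e-10	TRUE	2	4.4e-8	FALSE	0.5	IIB
Oxidative_Damage	tsa1	3.9e-9	FALSE	18	3.5e-6	FALSE	42	IA
Telomere_Synthesis	est2	1.2e-10	FALSE	0.5	4.5e-8	FALSE	0.5	IIB
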