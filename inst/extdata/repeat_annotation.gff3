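##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-10-02
ChrIII	rtracklayer	long_terminal_repeat	151501	151832	.	+	.	ID=YCRWdelta10;element_type=solo_delta_Ty1
ChrIII	rtracklayer	long_terminal_repeat	152001	152332	.	+	.	ID=YCRWdelta11;element_type=solo_delta_Ty2
ChrIII	rtracklayer	long_terminal_repeat	169204	169540	.	+	.	ID=YCRWdelta10B;element_type=partial_delta
ChrV	rtracklayer	long_terminal_repeat	8001	8332	.	+	.	ID=YELWdelta1;element_type=solo_delta_Ty1
ChrV	rtracklayer	LTR_retrotransposon	30081	35997	.	-	.	ID=Ty912;element_type=full_Ty1
ChrV	rtracklayer	long_terminal_repeat	431543	431874	.	-	.	ID=YERCdelta14;element_type=solo_delta_Ty1
ChrV	rtracklayer	long_terminal_repeat	438901	439232	.	+	.	ID=YERWdelta17;element_type=solo_delta_Ty1
ChrV	rtracklayer	LTR_retrotransposon	442901	448817	.	-	.	ID=YERCTy1-1;element_type=full_Ty1
ChrV	rtracklayer	long_terminal_repeat	449317	449625	.	+	.	ID=YERWdelta20B;element_type=partial_delta
ChrX	rtracklayer	LTR_retrotransposon	478701	484617	.	+	.	ID=YJRWTy1-1;element_type=full_Ty1
ChrX	rtracklayer	LTR_retrotransposon	484801	490717	.	+	.	ID=YJRWTy1-2;element_type=full_Ty1
ChrXII	rtracklayer	LTR_retrotransposon	651101	657017	.	+	.	ID=YLRWTy1-3;element_type=full_Ty1
ChrXII	rtracklayer	long_terminal_repeat	700951	701282	.	-	.	ID=YLRCdelta9;element_type=solo_delta_Ty1
ChrXII	rtracklayer	LTR_retrotransposon	701501	707417	.	+	.	ID=YLRWTy1-2;element_type=full_Ty1
ChrXII	rtracklayer	long_terminal_repeat	707601	707932	.	-	.	ID=YLRCdelta12;element_type=solo_delta_Ty1
ChrXIII	rtracklayer	LTR_retrotransposon	184001	189917	.	+	.	ID=YMLWTy1-1;element_type=full_Ty1
ChrXIII	rtracklayer	LTR_retrotransposon	196101	202017	.	+	.	ID=YMLWTy1-2;element_type=full_Ty1
ChrXVI	rtracklayer	LTR_retrotransposon	857001	862917	.	+	.	ID=YPRWTy1-3;element_type=full_Ty1
ChrXVI	rtracklayer	long_terminal_repeat	863101	863432	.	-	.	ID=YPRCdelta22;element_type=solo_delta_Ty1
ChrXVI	rtracklayer	LTR_retrotransposon	863601	869517	.	-	.	ID=YPRCTy1-4;element_type=full_Ty1
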