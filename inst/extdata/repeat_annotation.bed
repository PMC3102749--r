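ChrIII	151500	151832	YCRWdelta10|solo_delta_Ty1	0	+
ChrIII	152000	152332	YCRWdelta11|solo_delta_Ty2	0	+
ChrIII	169203	169540	YCRWdelta10B|partial_delta	0	+
ChrV	8000	8332	YELWdelta1|solo_delta_Ty1	0	+
ChrV	30080	35997	Ty912|full_Ty1	0	-
ChrV	431542	431874	YERCdelta14|solo_delta_Ty1	0	-
ChrV	438900	439232	YERWdelta17|solo_delta_Ty1	0	+
ChrV	442900	448817	YERCTy1-1|full_Ty1	0	-
ChrV	449316	449625	YERWdelta20B|partial_delta	0	+
ChrX	478700	484617	YJRWTy1-1|full_Ty1	0	+
ChrX	484800	490717	YJRWTy1-2|full_Ty1	0	+
ChrXII	651100	657017	YLRWTy1-3|full_Ty1	0	+
ChrXII	700950	701282	YLRCdelta9|solo_delta_Ty1	0	-
ChrXII	701500	707417	YLRWTy1-2|full_Ty1	0	+
ChrXII	707600	707932	YLRCdelta12|solo_delta_Ty1	0	-
ChrXIII	184000	189917	YMLWTy1-1|full_Ty1	0	+
ChrXIII	196100	202017	YMLWTy1-2|full_Ty1	0	+
ChrXVI	857000	862917	YPRWTy1-3|full_Ty1	0	+
ChrXVI	863100	863432	YPRCdelta22|solo_delta_Ty1	0	-
ChrXVI	863600	869517	YPRCTy1-4|full_Ty1	0	-
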