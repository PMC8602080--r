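class	label	motif	spacing	reference_count
Q	Q	QALGGH	CX(2)CX(12)HX(2,3,4)H	147
M	M1	ALGGH	CX(2)CX(12)HX(3)H	8
M	M2	Q_LGGH	CX(2)CX(12)HX(3)H	4
M	M3	LGGH	CX(2)CX(12)HX(3)H	6
M	M4	QALG_H	CX(2)CX(11,12)HX(2,3,4)H	7
M	M5	QA_GGH	CX(2)CX(12)HX(3)H	1
M	M6	AL_GH	CX(2)CX(12)HX(3)H	5
M	M7	L_GH	CX(1,2)CX(12,17)HX(3,4,6)H	3
M	M8	A__GH	CX(2)CX(12)HX(3)H	4
M	M9	ALG_H	CX(2)CX(12)HX(3,4)H	2
M	M11	Q_LG_H	CX(2)CX(12)HX(3)H	1
M	M10	LG_H	CX(2,4)CX(12)HX(3,4)H	6
Z	Z1	NKKFKSDKQWKNHEQSKKH	CX(2)CX(12)HX(5)H	5
Z	Z2A	GFQR_QNLQ_HRR_H	CX(2)CX(12)HX(3)H	22
Z	Z2B	KTFNR_NNMQMHMWGH	CX(2)CX(12)HX(3)H	9
Z	Z2C	GKGF_RDANLRMHMR_H	CX(2)CX(12)HX(3)H	5
Z	Z3A	HH____ALGDL_GIKKH__RKH	CX(4)CX(17)HX(4)H	21
Z	Z3B	RN___HPRARPLKDFRTLQTHY_RKH	CX(3)CX(20)HX(4)H	10
Z	Z3C	KRNK_H__FQPLKTILCVKNHYK_SH	CX(4)CX(20)HX(4)H	4
Z	Z4A	K_YAV_SD_KAHLKTCGTRGH	CX(2)CX(12)HX(8)H	5
Z	Z4B	K_YAV__D_KAH_K	CX(2)CX(12)HX(2)	16
Z	Z4C	K_FS__ADL_THEKH	CX(2)CX(13)HX(2)H	4
Z	Z4D	K_FAV_GDWRTHEK	CX(2)CX(12)HX(2,5)	10
Z	Z5A	GSEFKHKRSLKDHARAFGH	CX(1)CX(12)HX(5)H	2
Z	Z5B	GS_FKHKRSL_DH_R_FG	CX(1)CX(12)HX(4,5)	8
Z	Z6	VVRSKKCL__AH	CX(3)CX(12)HX(3)H	4
Z	Z7	S__G___EL_KH	CX(4)CX(11)HX(4)H	4
Z	Z8	TKLFHA_EFV_KH__LKH	CX(4)CX(12)HX(4)H	4
Z	Z9	DKAYIH_YKLNLHLK__H	CX(4)CX(12)HX(4)H	3
Z	Z10	K_F___SKLK_H	CX(4)CX(12)HX(3)H	5
Z	Z11	G__F_K_AHLKQHMQSH	CX(2)CX(12)HX(3)H	4
Z	Z12	G_AFSLDFNL__H	CX(4)CX(12)HX(3)H	3
Z	Z13	F__VSD__RH	CX(4)CX(12)HX(2,4)H	4
C	C		CX(1,2,4)CX(10,11,12,13,14,15,16,17)HX(1,2,3,4,5,6,7)H	126
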