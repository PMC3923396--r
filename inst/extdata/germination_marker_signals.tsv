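gene_id	annotation	0	12	24	36	48
CK202188	Signaling (CLV1)	169.4	233.8	739.1	642.5	920.4
BJ272365	Development (WUS)	855	1327.5	1869.6	1641.7	2129
CK201893	Redox (RML1)	1197.5	3513.7	4029.8	6636.6	7191.3
CD869453	RNA (STM)	78.1	171.6	701.5	931.5	512.9
CD866884	PPFK	2402.5	16708	4057.1	3532	4693.6
BJ252827	PK	874.9	12434.8	2758.3	2533.1	2731.5
CK207050	PK	817.4	12462.8	3732.2	3005.6	2940.7
CD491538	UGPase	95.6	65.1	340.7	416.1	464.5
CD868238	ADH	46.5	18628.9	7036.5	6872.1	11337.4
CD934753	PDC	26377	29397.3	24081.2	21766.5	22919.1
CA719001	AMY1/ATAMY1	216.9	107.8	11673.8	17917.4	15255.9
AL820663	AMY1/ATAMY1	436.2	187.7	16939.6	22679.4	16296.5
BF293263	AMY1/ATAMY1	90.1	19.8	4794.2	10521.7	3553.7
CD490513	Embryonic abundant protein 1	8096.9	3918.1	411.2	11	15
CD452864	CAX3 (cation exchanger 3)	3725.7	3014.4	1492.8	1087.4	1101.8
CK208119	CYP78A8 (cytochrome P450, family78, subfamilyA, polypeptide 8)	1162.8	600.6	242.6	173.6	154.8
CK216168	Ethylene forming enzyme	131.1	1223.2	2211.7	3156.8	2767.1
BJ291458	UBQ3 (Polyubiquitin 3)	1894.2	698.1	261.5	124.8	141.7
BJ282439	Ubiquitin E3	2361.7	2223.4	1081.8	906.4	767.7
CD453856	Chaperonin; folding	560.8	1558.8	3795.8	3980.4	3377.9
CD373830	Zinc transporter	1018.6	1032.4	627.1	505.7	450.9
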