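feature	label	lower	upper
BP10MB	BP10MB[0]	-Inf	0
BP10MB	BP10MB[1]	0	1
BP10MB	BP10MB[2]	1	2
BP10MB	BP10MB[3]	2	3
BP10MB	BP10MB[4]	3	4
BP10MB	BP10MB[5]	4	5
BP10MB	BP10MB[>5]	5	Inf
BPArm	BPArm[0]	-Inf	0
BPArm	BPArm[1]	0	1
BPArm	BPArm[2]	1	2
BPArm	BPArm[3]	2	3
BPArm	BPArm[4]	3	4
BPArm	BPArm[5]	4	5
BPArm	BPArm[6]	5	6
BPArm	BPArm[7]	6	7
BPArm	BPArm[8]	7	8
BPArm	BPArm[9]	8	9
BPArm	BPArm[10]	9	10
BPArm	BPArm[>10]	10	Inf
CN	CN[0]	-Inf	0
CN	CN[1]	0	1
CN	CN[2]	1	2
CN	CN[3]	2	3
CN	CN[4]	3	4
CN	CN[5]	4	5
CN	CN[6]	5	6
CN	CN[7]	6	7
CN	CN[8]	7	8
CN	CN[>8]	8	Inf
CNCP	CNCP[0]	-Inf	0
CNCP	CNCP[1]	0	1
CNCP	CNCP[2]	1	2
CNCP	CNCP[3]	2	3
CNCP	CNCP[4]	3	4
CNCP	CNCP[5]	4	5
CNCP	CNCP[6]	5	6
CNCP	CNCP[7]	6	7
CNCP	CNCP[>7]	7	Inf
OsCN	OsCN[0]	-Inf	0
OsCN	OsCN[1]	0	1
OsCN	OsCN[2]	1	2
OsCN	OsCN[3]	2	3
OsCN	OsCN[4]	3	4
OsCN	OsCN[>4]	4	Inf
NC50	NC50[<=2]	-Inf	2
NC50	NC50[3]	2	3
NC50	NC50[4]	3	4
NC50	NC50[5]	4	5
NC50	NC50[6]	5	6
NC50	NC50[7]	6	7
NC50	NC50[>7]	7	Inf
SS	SS[>3 & <=4]	-Inf	4
SS	SS[>4 & <=5]	4	5
SS	SS[>5 & <=6]	5	6
SS	SS[>6 & <=7]	6	7
SS	SS[>7 & <=8]	7	8
SS	SS[>8]	8	Inf
BoChr	BoChr[1]	-Inf	1
BoChr	BoChr[2]	1	2
BoChr	BoChr[3]	2	3
BoChr	BoChr[4]	3	4
BoChr	BoChr[5]	4	5
BoChr	BoChr[6]	5	6
BoChr	BoChr[7]	6	7
BoChr	BoChr[8]	7	8
BoChr	BoChr[9]	8	9
BoChr	BoChr[10]	9	10
BoChr	BoChr[11]	10	11
BoChr	BoChr[12]	11	12
BoChr	BoChr[13]	12	13
BoChr	BoChr[14]	13	14
BoChr	BoChr[15]	14	15
BoChr	BoChr[16]	15	16
BoChr	BoChr[17]	16	17
BoChr	BoChr[18]	17	18
BoChr	BoChr[19]	18	19
BoChr	BoChr[20]	19	20
BoChr	BoChr[21]	20	21
BoChr	BoChr[22]	21	22
BoChr	BoChr[23]	22	Inf
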