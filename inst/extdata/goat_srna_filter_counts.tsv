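sample	total_reads	low_quality	adaptor3_null	insert_null	adaptor5_contaminant	size_lt_18	polyA
T1	12269110	30829	28448	46229	1077	58052	6
T2	11034263	33284	110453	132781	2468	129083	30
T3	10433558	42878	139022	214081	8713	190887	821
A1	11305511	28265	20273	37755	840	60332	18
A2	10262585	45949	121601	131464	8354	190460	549
A3	10943292	27071	25327	35990	1239	59557	24
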