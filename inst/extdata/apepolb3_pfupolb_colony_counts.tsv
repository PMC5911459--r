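label	total_colonies	mutant_colonies	mf_override
ApePolB3-1	9810	966	0.0896
ApePolB3-2	2422	234	0.0881
ApePolB3-3	2065	361	0.1488
ApePolB3-4	2167	280	0.1144
ApePolB3-5	2923	396	0.1193
PfuPolB-1	2019	51	0.0246
PfuPolB-2	1929	23	0.0118
PfuPolB-3	2376	17	0.0071
PfuPolB-4	2900	20	0.0068
PfuPolB-5	2159	16	0.0074
Background	3599	22	0.0061
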