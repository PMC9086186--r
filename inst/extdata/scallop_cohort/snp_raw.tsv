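sample_id	snp_number	transition	transversion	ts_tv
Control_1	5734870	2994839	2649234	1.13
Control_2	5962010	3114468	2754571	1.13
Control_3	5888822	3075869	2721273	1.13
Control_4	5879675	3075363	2711445	1.13
Treated_1	5595911	2927478	2576977	1.14
Treated_2	5655161	2958453	2606812	1.13
Treated_3	5174423	2699803	2377189	1.14
Treated_4	5769920	3016864	2662803	1.13
Treated_5	5658279	2961110	2606843	1.14
Treated_6	5704352	2985503	2628324	1.14
Treated_7	5404289	2820629	2488661	1.13
Treated_8	5635551	2942406	2602225	1.13
Treated_9	6012300	3141694	2778385	1.13
Treated_10	5037014	2622721	2320483	1.13
Treated_11	5913470	3095125	2728073	1.13
Treated_12	5956325	3110318	2754478	1.13
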