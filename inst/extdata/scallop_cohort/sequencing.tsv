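sample_id	clean_read_pairs	clean_bases
Control_1	72397388	10730101234
Control_2	86746906	12841328031
Control_3	78575284	11637694182
Control_4	80070256	11846376980
Treated_1	67832690	10041975926
Treated_2	64159190	9470920591
Treated_3	63990224	9454811079
Treated_4	65044560	9615563726
Treated_5	67712528	10006244700
Treated_6	65341510	9667122876
Treated_7	66519728	9826753951
Treated_8	66587084	9863157597
Treated_9	78747896	11665293124
Treated_10	64408982	9530201612
Treated_11	68486448	10122154287
Treated_12	74752348	11073164954
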