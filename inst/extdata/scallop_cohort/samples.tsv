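sample_id	group	length_mm	height_mm	width_mm
Control_1	control	66	65	31
Control_2	control	65	64	31
Control_3	control	65	63.5	31
Control_4	control	64	63	30
Treated_1	treated_large	79.5	77	31
Treated_2	treated_large	77	66	32
Treated_3	treated_large	77	76	32
Treated_4	treated_large	77	76	33
Treated_5	treated_large	77	77	31
Treated_6	treated_normal	66	64	31
Treated_7	treated_normal	65	65.5	29
Treated_8	treated_normal	64	51.5	29
Treated_9	treated_normal	63	51	29
Treated_10	treated_normal	59	58	28
Treated_11	treated_small	51	49	28
Treated_12	treated_small	50	49.5	28.5
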