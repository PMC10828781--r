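cross	te_status	n_60_90	n_90_120	n_120_150	expected_ratio	tested_classes
Yangzhou431_x_Zhong07-4Xi-28	without_te	9	31	19	1:2:1	60_90,90_120,120_150
Yangzhou431_x_Zhong07-4Xi-28	with_te	36	20	0	1:2:1	60_90,90_120,120_150
Zhaohui_x_Zhong09-1Xi-28	without_te	6	50	75	1:1	90_120,120_150
Zhaohui_x_Zhong09-1Xi-28	with_te	32	54	1	1:1	90_120,120_150
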