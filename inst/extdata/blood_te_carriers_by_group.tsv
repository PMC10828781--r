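category	group	n_accessions	n_with_te
wild	Wild varieties	13	0
landrace	Northwest China group	20	0
landrace	Yun-gui plateau group	18	0
landrace	Northeast China group	9	0
landrace	China North Plain group	20	7
landrace	Yangtze River middle and lower reaches group	22	10
landrace	South China subtropical area group	10	0
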