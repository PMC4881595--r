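study	species	count	n_up	n_down
E-MEXP-2547	mouse	179	179	0
GSE23160	mouse	22	22	0
GSE30655	mouse	341	128	213
GSE58720	mouse	1162	841	321
E-MEXP-2222	rat	83	81	2
GSE33725	rat	38	38	0
GSE52001	rat	94	66	28
GSE61616	rat	827	695	132
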