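sample_id	n_cdna_sequences	chr5q15_K-31_pct	chr3q21.2_K-4_pct
32-Mot	1	100	0
35-Mot	6	100	0
357-SC	18	100	0
5847-SC	2	100	0
802-SC	13	100	0
23-Mot	23	100	0
5458-SC	4	75	25
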