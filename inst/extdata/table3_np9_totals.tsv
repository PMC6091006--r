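sample_id	n_cdna_sequences
32-Mot	64
35-Mot	19
357-SC	17
5847-SC	7
802-SC	13
5458-SC	24
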