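sample_id	n_cdna_sequences
89-Mot	16
62-Mot	40
64-Mot	10
802-SC	25
1509-Mot	13
73-Mot	15
4263-SC	25
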