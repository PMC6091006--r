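group	n_cdna_sequences	n_samples
ALS_motor	318	11
ALS_occipital	134	6
ALS_spinal_cord	70	2
Ctrl_motor	138	5
Ctrl_occipital	96	2
Ctrl_spinal_cord	64	2
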