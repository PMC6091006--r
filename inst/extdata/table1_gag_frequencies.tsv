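locus_id	ALS_motor	ALS_occipital	ALS_spinal_cord	Ctrl_motor	Ctrl_occipital	Ctrl_spinal_cord
chr3q12.3_K-5	52.20	39.55	58.57	60.14	52.08	64.06
chr3q21.2_K-4	11.01	15.67	7.14	13.04	13.54	1.56
chr7q34_K-15	8.49	9.70	8.57	9.42	10.42	4.69
chr19q13.12_K-29	6.92	8.21	11.43	3.62	10.42	0.00
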