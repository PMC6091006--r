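locus_id	89-Mot	62-Mot	64-Mot	802-SC	1509-Mot	73-Mot	4263-SC
chr3q12.3_K-5	62.50	77.50	70.00	28.00	53.85	40.00	40.00
chr1q22_K-7|chr5q33.3_K-10	31.25	12.50	20.00	24.00	15.38	13.33	32.00
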