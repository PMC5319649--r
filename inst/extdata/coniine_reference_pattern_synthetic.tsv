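mz	rel_intensity
56	0.42
70	0.38
80	0.35
84	1.00
126	0.10
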