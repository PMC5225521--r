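>SYN_CAGACA 6
0.9	15.3	0.9	0.9
15.3	0.9	0.9	0.9
0.9	0.9	15.3	0.9
15.3	0.9	0.9	0.9
0.9	15.3	0.9	0.9
15.3	0.9	0.9	0.9
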