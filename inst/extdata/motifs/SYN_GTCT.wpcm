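>SYN_GTCT 4
0.6	0.6	10.2	0.6
0.6	0.6	0.6	10.2
0.6	10.2	0.6	0.6
0.6	0.6	0.6	10.2
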