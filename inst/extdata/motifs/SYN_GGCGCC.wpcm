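>SYN_GGCGCC 6
1	1	17	1
1	1	17	1
1	17	1	1
1	1	17	1
1	17	1	1
1	17	1	1
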