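>SYN_RAND5 5
10.002078464	4.754739199	11.342178364	9.401003973
0.02104017091	0.04562661536	29.10002373406	6.33330947967
28.0609372441	3.2094738496	4.0104958794	0.2190930269
11.885706439	2.418266006	17.937194924	3.258832632
3.598901591	27.722670569	0.013083427	4.165344413
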