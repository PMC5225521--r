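>SYN_RAND10 10
7.4565749156720	3.4637287411563	0.0004534641465	24.5792428790252
1.673145269881	22.934039943549	0.005601518923	10.887213267647
5.2431264885	10.6041793944	18.9001512847	0.7525428324
6.0940622475	0.4698039812	9.7053642162	19.2307695551
3.0340015073	8.0093221508	24.0632421290	0.3934342129
4.282405416	4.478451994	12.089033890	14.650108701
5.317548970	6.057725558	21.900628933	2.224096538
1.279088060	3.260209342	18.112812565	12.847890032
25.6664296105	4.7500053790	4.6248548533	0.4587101572
0.1838203816	9.7710098102	13.9870554535	11.5581143547
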