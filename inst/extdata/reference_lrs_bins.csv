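offspring,n
0,13440
1,6413
2,1702
3,481
4,269
5,182
6,126
7,122
8,92
9,65
10,54
11,42
12,37
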