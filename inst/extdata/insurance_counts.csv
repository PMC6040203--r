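claims,count
0,7840
1,1317
2,239
3,42
4,14
5,4
6,4
7,1
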