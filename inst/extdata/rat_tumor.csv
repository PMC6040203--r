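y,n
0,20
0,20
0,20
0,20
0,20
0,20
0,20
0,19
0,19
0,19
0,19
0,18
0,18
0,17
1,20
1,20
1,20
1,20
1,19
1,19
1,18
1,18
3,27
2,25
2,24
2,23
2,20
2,20
2,20
2,20
2,20
2,20
1,10
5,49
2,19
5,46
2,17
7,49
7,47
3,20
3,20
2,13
9,48
10,50
4,20
4,20
4,20
4,20
4,20
4,20
4,20
10,48
4,19
4,19
4,19
5,22
11,46
12,49
5,20
5,20
6,23
5,19
6,22
6,20
6,20
6,20
16,52
15,46
15,47
9,24
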