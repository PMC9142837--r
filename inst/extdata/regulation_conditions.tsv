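index	a:none,r:none	a:none,r:some	a:none,r:all	a:some,r:none	a:some,r:some	a:some,r:all	a:all,r:none	a:all,r:some	a:all,r:all
0	0	0	0	0	0	0	1	0	0
1	0	0	0	0	0	0	1	1	0
2	0	0	0	0	0	0	1	1	1
3	0	0	0	1	0	0	1	0	0
4	0	0	0	1	0	0	1	1	0
5	0	0	0	1	0	0	1	1	1
6	0	0	0	1	1	0	1	1	0
7	0	0	0	1	1	0	1	1	1
8	0	0	0	1	1	1	1	1	1
9	1	0	0	1	0	0	1	0	0
10	1	0	0	1	0	0	1	1	0
11	1	0	0	1	0	0	1	1	1
12	1	0	0	1	1	0	1	1	0
13	1	0	0	1	1	0	1	1	1
14	1	0	0	1	1	1	1	1	1
15	1	1	0	1	1	0	1	1	0
16	1	1	0	1	1	0	1	1	1
17	1	1	0	1	1	1	1	1	1
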