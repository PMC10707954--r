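group,p1,p2,p3,p4,p5,p6,p7,p8,p9,p10,p11,p12,p13,p14,p15,p16,p17,printed_mr
1,178,0,0,0,0,0,1,0,0,0,0,0,0,0,10,0,0,6
2,1,56,0,0,0,0,1,0,0,0,0,0,0,0,2,0,0,7
3,0,2,13,0,0,0,0,0,0,0,0,0,0,0,2,0,0,24
4,0,0,0,101,0,1,0,0,0,1,0,0,0,0,1,0,1,4
5,1,2,0,1,38,1,1,0,0,0,0,0,1,0,1,0,0,17
6,2,5,0,1,0,366,4,1,0,0,0,0,0,0,0,0,2,4
7,1,4,1,0,2,3,130,2,0,0,0,0,0,0,0,0,2,10
8,1,0,0,0,0,6,1,45,0,1,0,0,0,0,1,0,0,18
9,0,2,0,0,0,6,0,2,46,0,0,0,0,0,0,0,0,18
10,2,0,0,1,1,1,0,1,1,443,2,0,0,0,0,0,1,2
11,1,0,0,0,0,0,0,0,0,11,298,0,0,0,0,0,0,4
12,0,0,0,0,0,0,0,0,0,0,0,22,0,0,1,0,0,4
13,1,0,0,0,0,0,1,0,0,2,2,0,45,1,6,0,0,22
14,0,0,0,0,0,0,0,0,0,1,1,0,0,29,0,0,0,6
15,6,3,1,0,0,0,1,0,0,0,0,0,2,0,163,0,0,7
16,0,0,0,1,0,6,1,0,0,0,0,0,0,0,1,12,1,48
17,2,0,0,2,0,7,1,0,0,1,1,1,0,0,1,1,75,19
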