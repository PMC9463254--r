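segment_id,artery,fraction
1,LAD,1
2,LAD,0.7
2,RCA,0.3
3,LAD,0.3
3,RCA,0.7
4,RCA,0.8
4,LCx,0.2
5,LCx,1
6,LAD,0.3
6,LCx,0.7
7,LAD,1
8,LAD,0.7
8,RCA,0.3
9,LAD,0.3
9,RCA,0.7
10,RCA,0.8
10,LCx,0.2
11,RCA,0.2
11,LCx,0.8
12,LAD,0.3
12,LCx,0.7
13,LAD,1
14,LAD,0.7
14,RCA,0.3
15,LAD,0.2
15,RCA,0.6
15,LCx,0.2
16,LAD,0.3
16,LCx,0.7
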