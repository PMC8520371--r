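week,p10_weight_g
24,550
25,650
26,760
27,880
28,1010
29,1150
30,1300
31,1460
32,1620
33,1790
34,1960
35,2130
36,2290
37,2430
38,2560
39,2670
40,2760
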