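"age_years","value"
0,7
0.5,10
1,13
2,17
5,26
10,40
15,57
20,70
25,72
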