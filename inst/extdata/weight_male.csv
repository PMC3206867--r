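"age_years","value"
0,3.5
0.5,8
1,10.3
2,12.7
5,18.5
10,32
15,56.5
20,71
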