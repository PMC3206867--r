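"age_years","value"
0,3.4
0.5,7.3
1,9.5
2,12.1
5,18
10,33
15,52
20,58
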