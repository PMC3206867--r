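age_years,value
0.0,2800.000000000000
0.5,2545.000000000000
1.0,2111.000000000000
2.0,1654.000000000000
5.0,1095.000000000000
10.0,965.000000000000
15.0,896.000000000000
20.0,763.864285714286
25.0,740.000000000000
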