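component,p_men,p_women,alpha_men,alpha_women
1,0.0556,0.0185,70.32,77.27
2,0.1841,0.1112,71.19,78.08
3,0.1529,0.2655,71.76,78.54
4,0.2711,0.1978,72.23,78.84
5,0.1700,0.1684,72.72,79.29
6,0.0922,0.2016,73.07,79.63
7,0.0740,0.0371,73.71,80.22
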