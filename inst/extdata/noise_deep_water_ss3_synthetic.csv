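"freq_khz","spectral_db"
1,62
2,56.882
5,50.118
10,45
20,39.888
32.5,36.332
50,33.282
65,31.602
80,30.509
100,29.764
115,29.618
130,29.724
150,30.121
175,30.836
200,31.641
250,33.241
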