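cbt_mm,mGy
20,0.6
30,0.7
40,0.9
50,1.2
60,1.6
70,2.2
80,2.9
90,3.8
100,4.8
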