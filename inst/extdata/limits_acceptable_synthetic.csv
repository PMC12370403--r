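cbt_mm,mGy
20,1.0
30,1.2
40,1.5
50,2.0
60,2.7
70,3.6
80,4.7
90,6.0
100,7.5
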