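"conc_uM","fluorescence"
0,1.00286060694658
2,0.95705446158974
5,0.9098709697423
10,0.812335730026796
20,0.698280129357181
40,0.564245093978161
80,0.430461154417505
150,0.33647117282786
300,0.249480843334011
450,0.251291945759923
600,0.244384443658357
800,0.230553085328018
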