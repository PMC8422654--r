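LM=3
0.0 0.0
4.2 0.1
3.9 1.8
CURVES=1
POINTS=4
0.0 0.0
1.5 1.2
2.8 1.6
3.9 1.8
ID=example_specimen_1
SCALE=0.01
LM=3
0.1 0.0
4.0 0.2
3.7 1.9
ID=example_specimen_2
SCALE=0.01
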