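"G","H","I","T","E","B","S","C"
0.01875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875,0.86875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.86875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875
0.01875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875,0.86875
0.01875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875,0.86875
0.01875,0.01875,0.01875,0.01875,0.01875,0.01875,0.01875,0.86875
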