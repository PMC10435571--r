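>SYN0001.1 GATA1_synthetic
A  [ 30  25  30   3  97   1  95  50  30  31  28 ]
C  [ 20  25   5   1   1   1   2   3  15  23  26 ]
G  [ 25  20   5  95   1   1   2  45  40  23  24 ]
T  [ 25  30  60   1   1  97   1   2  15  23  22 ]
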