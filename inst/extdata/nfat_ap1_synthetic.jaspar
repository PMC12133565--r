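>NFAT_AP1_synth NFAT:AP1 composite (synthetic stand-in)
A  [   4   3   2   4   5  60  30   5   4  88   5   4   5  90 ]
C  [   3   2   2  90  88  10  20   5   3   4  45   3  88   4 ]
G  [   3   3   2   3   3  20  25   5  90   4  45   3   3   3 ]
T  [  90  92  94   3   4  10  25  85   3   4   5  90   4   3 ]
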