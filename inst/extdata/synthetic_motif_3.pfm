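>SYN0003 synthetic_fungal_motif_3
A  [  1  1 14  1  1  1  1 ]
C  [  1  1  1  1 17 15  4 ]
G  [  1  1  5 15  1  1 17 ]
T  [ 17 16  1  1  1  1  1 ]
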