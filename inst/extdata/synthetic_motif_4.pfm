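>SYN0004 synthetic_fungal_motif_4
A  [  1 18  1 15 18  3 14 ]
C  [  1  1  1  1  1  1  4 ]
G  [ 16  1  1  1  1 15  1 ]
T  [  3  1 15  4  4  1  1 ]
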