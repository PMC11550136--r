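>SYN0005 synthetic_fungal_motif_5
A  [  1  5  1  1 18  1  1  1 ]
C  [ 14 17  1  1  1 15  1  1 ]
G  [  1  1 16  1  1  1 14 18 ]
T  [  1  1  1 18  1  1  1  1 ]
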