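>SYN0006 synthetic_fungal_motif_6
A  [  1  1 15  1  1  1  1 14  1 ]
C  [  1  1  1  1  1  1 17  1  1 ]
G  [  1 14  1  1  1 16  1  1  1 ]
T  [ 18  1  1 16 18  1  1  1 14 ]
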