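>SYN0002 synthetic_fungal_motif_2
A  [  1 15  1  5  1  1 ]
C  [ 17  1 16  1  1  1 ]
G  [  1  1  1 14  1 17 ]
T  [  1  1  1  1 18  1 ]
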