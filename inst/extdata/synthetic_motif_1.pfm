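>SYN0001 synthetic_fungal_motif_1
A  [  1  1 15  5  1  1 ]
C  [  1  1  1 15  1 18 ]
G  [  1 14  1  1  1  1 ]
T  [ 14  1  1  1 17  1 ]
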