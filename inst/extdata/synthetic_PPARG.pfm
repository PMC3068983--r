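>SYN_PPARG synthetic DR1-type direct repeat element (stand-in matrix, not a database PFM)
A [ 24  0  0  0  0 30 24 30  0  0  0  0 24 ]
C [  0  0  0  0 30  0  0  0  0  0  0 30  0 ]
G [  6 30 30  0  0  0  0  0 30 30  0  0  6 ]
T [  0  0  0 30  0  0  6  0  0  0 30  0  0 ]
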