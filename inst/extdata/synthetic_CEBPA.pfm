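>SYN_CEBPA synthetic C/EBP-type palindromic element (stand-in matrix, not a database PFM)
A [  6 30  0  0  0  0  0  0 30 30  0  0 ]
C [  0  0  0  0  0 30  0 30  0  0  0 24 ]
G [ 24  0  0  0 30  0 30  0  0  0  0  0 ]
T [  0  0 30 30  0  0  0  0  0  0 30  6 ]
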