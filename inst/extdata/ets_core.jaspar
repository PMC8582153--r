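>ETS_CORE synthetic ETS-family core motif (GGAA/T-centered)
A [ 70 10 70  5  2 95 95  5 10  5 ]
C [ 10 70 10  3  2  1  1  3 10  5 ]
G [ 10 10 10 90 95  2  2 90 10 85 ]
T [ 10 10 10  2  1  2  2  2 70  5 ]
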