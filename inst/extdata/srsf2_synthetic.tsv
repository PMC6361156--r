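factor	SRSF2_synthetic
threshold	6.5
A	0	0	0	0	0	0	1	0
C	0	0	0	1	0	0	0	0
G	1	1	0	0	0	1	0	1
T	0	0	1	0	1	0	0	0
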