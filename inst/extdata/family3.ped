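FAM3	FA	0	0	1	0
FAM3	MO	0	0	2	0
FAM3	S1	FA	MO	2	2
FAM3	S2	FA	MO	2	2
FAM3	S3	FA	MO	2	2
FAM3	S4	FA	MO	2	1
FAM3	S5	FA	MO	2	1
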