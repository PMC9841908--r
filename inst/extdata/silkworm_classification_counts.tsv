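tier	InFrameORF	OutFrameORF	dORF	intergenicORF	ncORF	uORF
HC1	165	259	10	130	161	13
HC2	1	1	0	10	0	0
HC3	2855	7534	982	7529	13286	1169
LC1	1	0	0	214	0	0
LC2	4	13	0	59	1	4
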