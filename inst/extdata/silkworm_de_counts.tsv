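tissue	ASG	FB	MG	MSG_A	MSG_M	MSG_P	MT	OV	PSG	SG	TT
ASG	0	4686	5159	3260	3589	3514	4379	5156	4148	9582	8545
FB	4686	0	4103	4356	4878	4772	4133	5201	5098	8685	8186
MG	5159	4103	0	4925	5413	5297	3339	6785	5649	9053	8839
MSG_A	3260	4356	4925	0	961	1149	4465	5120	1712	7919	8324
MSG_M	3589	4878	5413	961	0	171	5073	5794	1155	8461	8965
MSG_P	3514	4772	5297	1149	171	0	4935	5761	907	8677	9010
MT	4379	4133	3339	4465	5073	4935	0	5986	5183	9112	8579
OV	5156	5201	6785	5120	5794	5761	5986	0	6365	12340	6219
PSG	4148	5098	5649	1712	1155	907	5183	6365	0	8570	9003
SG	9582	8685	9053	7919	8461	8677	9112	12340	8570	0	12454
TT	8545	8186	8839	8324	8965	9010	8579	6219	9003	12454	0
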