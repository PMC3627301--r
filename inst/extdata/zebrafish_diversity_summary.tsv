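population	type	S	h	pi_pct	hs_snp
PAR	wild	25	0.87	0.88	0.154
KHA	wild	13	0.92	0.24	0.060
BER	wild	24	0.90	0.40	0.223
SHK	wild	16	0.89	0.53	NA
DHO	wild	NA	NA	NA	0.226
JOR	wild	13	0.64	0.26	0.224
PGM	wild	17	0.92	0.55	0.253
PNS	wild	20	0.83	0.55	0.272
UTR	wild	20	0.90	0.62	0.219
RCH	wild	67	0.89	1.30	0.215
CHT	wild	19	0.57	0.49	0.068
SRN	wild	0	NA	NA	NA
WYD	wild	1	NA	NA	NA
AB	lab	0	0	0	0.142
SJA	lab	0	0	0	0.027
TM1	lab	0	0	0	0.235
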