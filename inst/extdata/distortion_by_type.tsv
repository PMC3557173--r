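marker_type	total_loci	distorted	toward_recurrent	toward_heterozygote
eSSR	1450	140	70	70
gSSR	1284	73	29	44
REMAP	187	21	9	12
RT	172	22	6	16
SRAP	127	13	5	8
AFLP	80	24	14	10
SNP	73	4	3	1
CAPs	19	0	0	0
InDel	12	2	1	1
BAC-end	8	1	0	1
morphology	2	0	0	0
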