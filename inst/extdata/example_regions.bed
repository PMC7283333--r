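chr19	0	100000	R1	5.19
chr19	1200000	1300000	R2	6.47
chr19	2400000	2500000	R3	8.87
chr19	3600000	3700000	R4	12.9
chr19	4800000	4900000	R5	4.42
chr19	6000000	6100000	R6	12.78
chr19	7200000	7300000	R7	13.34
chr19	8400000	8500000	R8	9.93
chr19	9600000	9700000	R9	9.55
chr19	10800000	10900000	R10	2.74
chr19	12000000	12100000	R11	4.47
chr19	13200000	13300000	R12	4.12
chr19	14400000	14500000	R13	10.24
chr19	15600000	15700000	R14	6.61
chr19	16800000	16900000	R15	11.24
chr19	18000000	18100000	R16	7.97
chr19	19200000	19300000	R17	10.61
chr19	20400000	20500000	R18	13.9
chr19	21600000	21700000	R19	6.56
chr19	22800000	22900000	R20	11.33
chr19	24000000	24100000	R21	13.22
chr19	25200000	25300000	R22	4.55
chr19	26400000	26500000	R23	9.82
chr19	27600000	27700000	R24	3.51
chr19	28800000	28900000	R25	5.21
chr19	30000000	30100000	R26	6.63
chr19	31200000	31300000	R27	2.16
chr19	32400000	32500000	R28	6.59
chr19	33600000	33700000	R29	12.44
chr19	34800000	34900000	R30	6.08
chr19	36000000	36100000	R31	7.78
chr19	37200000	37300000	R32	9.19
chr19	38400000	38500000	R33	7.92
chr19	39600000	39700000	R34	4.23
chr19	40800000	40900000	R35	11.93
chr19	42000000	42100000	R36	10.02
chr19	43200000	43300000	R37	11.53
chr19	44400000	44500000	R38	3.3
chr19	45600000	45700000	R39	10.68
chr19	46800000	46900000	R40	6.94
chr19	48000000	48100000	R41	11.85
chr19	49200000	49300000	R42	9.76
chr19	50400000	50500000	R43	11.4
chr19	51600000	51700000	R44	8.64
chr19	52800000	52900000	R45	8.36
chr19	54000000	54100000	R46	11.47
chr19	55200000	55300000	R47	2.28
chr19	56400000	56500000	R48	7.73
chr19	57600000	57700000	R49	10.79
chr19	58800000	58900000	R50	10.31
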