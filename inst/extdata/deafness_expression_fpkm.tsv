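gene	control_fpkm	gentamicin_fpkm	log2fc_gentamicin	neomycin_fpkm	log2fc_neomycin
ush1g	0.44	0.10	-2.10	0.24	-0.86
pcdh15b	1.51	0.51	-1.58	0.39	-1.96
ptprq	0.49	0.07	-2.78	0.12	-2.02
col1a1a	1001.63	626.27	-0.68	466.45	-1.10
twist1a	40.15	24.23	-0.73	24.84	-0.69
diabloa	17.56	9.13	-0.94	8.42	-1.06
actb2	4882.95	2675.42	-0.87	2703.10	-0.85
tyr	55.70	33.88	-0.72	22.99	-1.28
lrtomt	0.63	0.31	-1.01	0.36	-0.81
fetub	1040.03	650.12	-0.68	369.93	-1.49
plekhm1	4.75	3.12	-0.60	2.98	-0.67
fgf10b	0.44	0.18	-1.30	0.22	-1.01
edn3	1.84	0.02	-6.53	0.97	-0.93
kctd1	2.32	0.93	-1.32	1.46	-0.67
apoa1b	5865.83	3853.52	-0.61	3544.56	-0.73
cldn2	1.05	0.58	-0.84	0.57	-0.88
dachc	6.26	4.07	-0.62	3.68	-0.77
fgf5	0.74	0.27	-1.46	0.22	-1.76
fgf20b	1.21	0.68	-0.84	0.66	-0.87
etv4	25.05	14.80	-0.76	12.94	-0.95
snai1b	4.79	2.98	-0.69	2.95	-0.70
her6	60.58	37.20	-0.70	34.28	-0.82
her12	116.63	62.82	-0.89	65.52	-0.83
tcf7l1a	37.23	24.73	-0.59	18.14	-1.04
jun	97.64	60.41	-0.69	36.52	-1.42
sfrp1b	19.61	9.56	-1.04	7.53	-1.38
climp-63	143.45	86.49	-0.73	72.02	-0.99
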