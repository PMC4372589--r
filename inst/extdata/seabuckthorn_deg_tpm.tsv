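gene	comparison	tpm1	tpm2	printed_log2
MAP2K	Control_vs_Cold	1.21	6.83	2.5
MAP2K	Control_vs_Freeze	1.21	8.31	2.8
ADC	Control_vs_Freeze	0.69	6.8	3.3
PP2c	Control_vs_Cold	0.01	1.42	7.1
PP2c	Cold_vs_Freeze	79.52	27.54	-1.5
PP2c	Control_vs_Freeze	0.52	2.86	2.5
AP2ERF	Control_vs_Cold	0.01	1.33	7.1
RPLP0	Control_vs_Cold	0.01	8.33	9.7
RPLP0	Control_vs_Freeze	8.33	0.01	-9.7
RPLP0	Control_vs_Freeze2	85.85	188.77	1.1
ATP19a	Control_vs_Cold	2.16	0.01	-7.8
ATP19a	Control_vs_Freeze	4.76	1.01	-2.2
ATP19a	Cold_vs_Freeze	3.75	1.09	-1.8
SAUR	Control_vs_Cold	4.93	0.92	-2.4
SAUR	Control_vs_Freeze	4.93	0.76	-2.7
HSP70	Cold_vs_Freeze	0.01	1.68	7.4
HSP70	Control_vs_Freeze	0.01	1.68	7.4
WD40	Control_vs_Cold	0.01	1.5	7.2
KCS	Control_vs_Cold	4.15	0.5	-3.1
KCS	Control_vs_Freeze	4.15	0.25	-4.1
PAP	Control_vs_Freeze	0.01	1.6	7.3
RNAh	Control_vs_Cold	0.01	1.58	7.3
CALM	Control_vs_Cold	0.01	3.41	8.4
CALM	Cold_vs_Freeze	26.98	6.3	-2.1
SIP2	Control_vs_Cold	4.93	17.98	1.9
SIP2	Cold_vs_Freeze	17.98	2.35	-3
CSP1	Control_vs_Cold	2.07	0.25	-3
CSP1	Cold_vs_Freeze	8.16	3.86	-1.1
CSP1	Control_vs_Freeze	3.11	0.01	-8.3
ABC	Control_vs_Cold	1.73	0.01	-7.4
SIZ1	Control_vs_Freeze	1.21	0.01	-6.9
KCS1	Control_vs_Cold	1.04	16.57	4
KCS1	Control_vs_Freeze	1.04	5.88	2.5
LIP	Control_vs_Freeze	0.01	1.6	7.3
LIP	Control_vs_Freeze2	4.58	11.25	1.3
SERAT	Control_vs_Cold	0.01	1.25	7
SERAT	Cold_vs_Freeze	45.13	2.27	-4.3
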