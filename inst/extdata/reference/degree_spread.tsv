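electrode	delta	theta	alpha1	alpha2	beta1	beta2	gamma1	gamma2
FP1	0.68	0.75	0.73	0.72	0.76	0.74	0.74	0.90
FP2	0.86	1.16	1.13	1.03	1.07	0.68	0.57	0.62
F3	0.10	0.29	0.28	0.31	0.20	0.28	0.28	0.13
FZ	0.43	0.50	0.24	0.52	0.27	0.32	0.54	0.38
F4	0.71	0.70	0.96	0.95	1.12	0.94	0.36	0.40
F8	0.88	1.09	0.67	0.47	0.38	0.34	0.40	0.37
FT7	0.63	0.46	0.44	0.45	0.30	0.20	0.29	0.22
FC3	0.16	0.32	0.21	0.26	0.27	0.40	0.17	0.20
C3	0.89	0.63	0.62	0.37	0.27	0.59	0.55	0.66
CZ	0.91	0.89	0.81	0.85	0.67	0.68	0.61	0.64
C4	0.75	0.71	0.52	0.32	0.50	0.26	0.15	0.20
CP3	0.71	0.56	0.36	0.17	0.20	0.28	0.63	0.81
CPZ	0.72	0.60	0.41	0.39	0.16	0.49	0.98	1.14
CP4	0.58	0.51	0.03	0.22	0.50	0.71	0.62	0.82
P3	0.38	0.41	0.19	0.13	0.32	0.57	0.56	0.11
PZ	0.53	0.16	0.17	0.10	0.31	0.18	0.28	0.55
P4	0.21	0.26	0.27	0.24	0.40	0.28	0.31	0.52
T3	0.95	0.83	0.52	0.60	0.43	0.24	0.14	0.09
T5	1.24	0.88	0.53	0.71	0.47	0.13	0.06	0.07
T4	1.40	1.60	1.22	0.72	0.34	0.26	0.22	0.28
TP8	0.78	1.00	0.63	0.64	0.23	0.08	0.06	0.00
T6	0.53	0.36	0.07	0.15	0.03	0.02	0.02	0.04
O1	0.75	0.44	0.32	0.41	0.09	0.21	0.22	0.18
OZ	0.61	0.53	0.60	0.61	0.45	0.50	0.37	0.32
O2	0.05	0.12	0.53	0.42	0.26	0.32	0.19	0.13
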