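metric	band	BF	LR	UD	SD
VDegree	delta	4.24	4.27	4.31	0.035
VDegree	theta	4.41	4.27	4.46	0.098
VDegree	alpha1	4.32	4.35	4.48	0.085
VDegree	alpha2	4.31	4.37	4.45	0.070
VDegree	beta1	4.30	4.29	4.39	0.055
VDegree	beta2	4.32	4.26	4.30	0.031
VDegree	gamma1	4.34	4.24	4.38	0.072
VDegree	gamma2	4.29	4.33	4.43	0.072
VPLength	delta	2.08	2.04	2.13	0.045
VPLength	theta	2.18	2.09	2.37	0.143
VPLength	alpha1	2.08	2.23	2.32	0.121
VPLength	alpha2	2.02	2.15	2.35	0.166
VPLength	beta1	1.89	2.07	2.16	0.137
VPLength	beta2	1.85	1.94	2.07	0.111
VPLength	gamma1	1.83	2.03	2.10	0.140
VPLength	gamma2	1.88	1.95	2.14	0.135
Cluster	delta	0.49	0.51	0.51	0.012
Cluster	theta	0.51	0.51	0.52	0.006
Cluster	alpha1	0.51	0.50	0.51	0.006
Cluster	alpha2	0.50	0.49	0.49	0.006
Cluster	beta1	0.49	0.50	0.49	0.006
Cluster	beta2	0.51	0.49	0.50	0.010
Cluster	gamma1	0.51	0.49	0.50	0.010
Cluster	gamma2	0.51	0.50	0.50	0.006
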