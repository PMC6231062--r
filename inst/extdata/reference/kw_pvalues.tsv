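electrode	delta	theta	alpha1	alpha2	beta1	beta2	gamma1	gamma2
FP1	0.03	0.007	0.006	0.013	0.003	0.003	0.006	0.001
FP2	0.001	0	0	0	0	0.002	0.006	0.003
F3	0.856	0.029	0.379	0.254	0.76	0.531	0.376	0.769
FZ	0.218	0.099	0.738	0.195	0.809	0.316	0.025	0.285
F4	0.032	0.003	0	0	0	0	0.032	0.013
F8	0.001	0	0	0.011	0.024	0.035	0.009	0.008
FT7	0.002	0.09	0.267	0.112	0.141	0.001	0	0.002
FC3	0.843	0.149	0.633	0.33	0.282	0.168	0.661	0.34
C3	0.009	0.024	0.025	0.213	0.594	0.006	0.023	0.072
CZ	0.006	0.014	0.051	0.006	0.055	0.05	0.033	0.016
C4	0.029	0.008	0.018	0.307	0.016	0.147	0.048	0.756
CP3	0.057	0.017	0.269	0.714	0.613	0.158	0.001	0
CPZ	0.054	0.005	0.215	0.529	0.918	0.079	0.002	0
CP4	0.003	0.009	0.893	0.83	0.422	0.014	0.007	0.006
P3	0.17	0.034	0.23	0.656	0.606	0.319	0.5	0.568
PZ	0.058	0.739	0.674	0.675	0.437	0.801	0.568	0.053
P4	0.714	0.326	0.268	0.237	0.009	0.013	0.071	0
T3	0.001	0.015	0.008	0	0	0.005	0.016	0.152
T5	0	0	0.009	0.004	0.003	0.102	0.604	0.23
T4	0.007	0.024	0	0	0	0.005	0.005	0.005
TP8	0	0	0	0	0.001	0.064	0.165	1
T6	0.003	0.033	0.217	0.238	0.348	0.368	0.368	0.132
O1	0.023	0.008	0.002	0.001	0.1891	0	NA	NA
OZ	0.005	0.003	0	0	0	0	NA	0
O2	0.834	0.805	0	0	0.009	0	0.067	0.248
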