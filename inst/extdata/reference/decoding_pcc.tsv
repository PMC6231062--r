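trajectory	model	axis	Subject1	Subject2	Subject3	Subject4	Subject5	Mean
SPIRAL1	MLR	R_x	0.7348	0.3481	0.4722	0.4199	0.4647	0.4824
SPIRAL1	MLR	R_y	0.5781	0.4872	0.6118	0.4772	0.6108	0.5465
SPIRAL1	MLR	R_z	0.6061	0.4369	0.3728	0.5788	0.4886	0.4257
SPIRAL1	MLR	R	0.6397	0.4241	0.4856	0.4920	0.5213	0.5125
SPIRAL1	HLM	R_x	0.5908	0.5895	0.5186	0.8233	0.7821	0.6609
SPIRAL1	HLM	R_y	0.8625	0.8224	0.8244	0.9955	0.7568	0.8523
SPIRAL1	HLM	R_z	0.6171	0.6735	0.5041	0.8712	0.6392	0.6610
SPIRAL1	HLM	R	0.6710	0.6332	0.5927	0.8606	0.7118	0.6939
SPIRAL2	MLR	R_x	0.8826	0.4059	0.7592	0.5715	0.6792	0.6597
SPIRAL2	MLR	R_y	0.3004	0.4440	0.4844	0.3205	0.2503	0.3600
SPIRAL2	MLR	R_z	0.5058	0.5296	0.6203	0.6598	0.4822	0.5595
SPIRAL2	MLR	R	0.5629	0.4598	0.6213	0.5172	0.4706	0.5264
SPIRAL2	HLM	R_x	0.5213	0.6084	0.9062	0.4426	0.7966	0.6550
SPIRAL2	HLM	R_y	0.7017	0.6085	0.7979	0.3297	0.4740	0.5824
SPIRAL2	HLM	R_z	0.6887	0.8823	0.9123	0.8826	0.7545	0.8241
SPIRAL2	HLM	R	0.6372	0.6997	0.8721	0.5516	0.6750	0.6871
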