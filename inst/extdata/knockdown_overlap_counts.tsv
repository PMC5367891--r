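factor	comparison	a	b	c	d	printed_or	or_tol	printed_p	p_tol
MAGOH	subtype_vs_kd	63	606	275	4243	1.6	0.005	0.0018	2e-4
MAGOHB	subtype_vs_kd	29	609	161	4256	1.26	0.005	0.2652	2e-4
PCBP2	subtype_vs_kd	47	611	183	4254	1.79	0.005	0.0012	2e-4
THOC1	subtype_vs_kd	403	551	2133	4005	1.37	0.005	9.20e-06	2e-8
YBX1	subtype_vs_kd	30	611	130	4260	1.61	0.005	0.0291	2e-4
YBX2	subtype_vs_kd	31	611	143	4260	1.51	0.005	0.0483	2e-4
MAGOH	er_binding_vs_kd	153	6695	568	29338	1.18	0.005	0.07	0.005
MAGOHB	er_binding_vs_kd	72	6776	270	29636	1.17	0.005	0.26	0.005
PCBP2	er_binding_vs_kd	65	6783	314	29592	0.9	0.05	0.51	0.005
THOC1	er_binding_vs_kd	1860	4988	6835	23071	1.26	0.005	7.69e-14	2e-16
YBX1	er_binding_vs_kd	69	6779	216	29690	1.4	0.05	0.018	0.0005
YBX2	er_binding_vs_kd	56	6792	194	29712	1.26	0.005	0.14	0.005
MAGOH	pr_binding_vs_kd	68	2387	653	33646	1.47	0.005	0.004	0.0005
MAGOHB	pr_binding_vs_kd	34	2421	308	33991	1.55	0.005	0.021	0.001
PCBP2	pr_binding_vs_kd	32	2423	347	33952	1.29	0.005	0.178	0.001
THOC1	pr_binding_vs_kd	688	1767	8007	26292	1.28	0.005	2.37e-07	2e-9
YBX1	pr_binding_vs_kd	29	2426	256	34043	1.59	0.005	0.023	0.001
YBX2	pr_binding_vs_kd	21	2434	229	34070	1.28	0.005	0.253	0.001
MAGOH	direction_kd_vs_subtype	4186	2192	1515	898	1.13	0.005	0.013	0.001
MAGOHB	direction_kd_vs_subtype	5390	1430	1658	814	1.85	0.005	2.20e-31	2e-33
PCBP2	direction_kd_vs_subtype	4111	1572	1232	798	1.69	0.005	7.10e-22	2e-24
THOC1	direction_kd_vs_subtype	3177	2978	1084	1003	0.99	0.005	0.8	0.01
YBX1	direction_kd_vs_subtype	5321	1738	1642	913	1.7	0.05	3.06e-26	2e-28
YBX2	direction_kd_vs_subtype	4292	1908	1466	802	1.23	0.005	7.09e-05	2e-7
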