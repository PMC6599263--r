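sample	msi_status	evolvability	split_ratio	doubling_time	growth_rate
C10	MSS	STABLE	0.34	2.33	0.30
C106	MSS	STABLE	0.35	2.50	0.28
C125PM	MSS	STABLE	0.34	2.37	0.29
C32	MSS	STABLE	0.18	1.54	0.45
C70	MSS	STABLE	0.40	2.76	0.25
C75	MSS	STABLE	0.36	2.46	0.28
CACO2	MSS	STABLE	0.26	1.83	0.38
CAR1	MSS	STABLE	0.36	2.47	0.28
CCK81	MSI	EVOLVING	0.34	2.53	0.27
COCM1	MSS	EVOLVING	0.30	2.34	0.30
COGA2	MSS	STABLE	0.32	2.22	0.31
COGA5	MSS	STABLE	0.20	1.69	0.41
COGA8	MSS	STABLE	0.22	1.67	0.41
COLO94H	MSS	STABLE	0.45	2.81	0.25
DLD1	MSI	EVOLVING	0.07	0.98	0.71
HCA24	MSS	EVOLVING	0.33	2.22	0.31
HCA46	MSS	STABLE	0.40	2.41	0.29
HCC2998	MSS	STABLE	0.34	2.33	0.30
HDC114	MSS	EVOLVING	0.23	1.69	0.41
HDC142	MSS	EVOLVING	0.35	2.42	0.29
HROC24	MSI	EVOLVING	0.16	1.23	0.56
HROC32	MSS	STABLE	0.62	6.07	0.11
HROC334	MSS	STABLE	0.45	2.83	0.24
HROC39	MSS	STABLE	0.50	3.92	0.18
HROC69	MSS	STABLE	0.33	2.26	0.31
HT115	MSS	EVOLVING	0.24	1.78	0.39
HT29	MSS	STABLE	0.16	1.38	0.50
HT55	MSS	STABLE	0.33	2.21	0.31
LIM1215	MSI	EVOLVING	0.15	1.24	0.56
LIM2099	MSS	STABLE	0.33	2.26	0.31
LS180	MSI	EVOLVING	0.25	1.90	0.37
LS411N	MSI	EVOLVING	0.32	2.29	0.30
MDST8	MSS	STABLE	0.15	1.31	0.53
OUMS23	MSS	STABLE	0.26	1.70	0.41
OXCO3	MSS	STABLE	0.23	1.76	0.39
RW7213	MSS	STABLE	0.40	2.60	0.27
SNU1040	MSI	EVOLVING	0.54	4.14	0.17
SNU1181	MSS	STABLE	0.62	4.65	0.15
SNU1235	MSS	EVOLVING	0.35	2.33	0.30
SNU1411	MSS	EVOLVING	0.44	2.76	0.25
SNU81	MSS	EVOLVING	0.42	2.33	0.30
SNU977	MSS	STABLE	0.42	2.71	0.26
SW480	MSS	STABLE	0.18	1.64	0.42
SW837	MSS	STABLE	0.27	2.07	0.34
V411	MSS	STABLE	0.22	1.91	0.36
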