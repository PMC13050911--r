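domain	group	n_core	taxo_mean_pct	taxo_se_pct	func_mean_pct	func_se_pct
bacteria	Self_open	2	0.005	0.006	3.63	0.85
bacteria	Self_bagging	1	0.007	0.006	8.17	5.43
bacteria	Cross_open	46	37.00	7.56	25.49	5.71
bacteria	Cross_bagging	2	0.74	0.49	2.20	0.53
fungi	Self_bagging	1	0.13	0.08	0.13	0.08
fungi	Cross_open	34	87.72	4.95	87.72	4.95
fungi	Cross_bagging	4	2.67	2.45	2.67	2.45
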