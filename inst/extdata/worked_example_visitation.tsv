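species	rate_mean_pct	rate_se_pct	n_reps	core_function_mean_pct_fungi
CA	64.94	1.01	5	NA
SM	90.04	1.67	5	NA
LA	83.01	2.87	5	85.02
MC	97.23	0.59	5	90.41
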