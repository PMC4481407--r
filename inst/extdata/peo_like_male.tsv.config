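# telofuse simulate config
sex	male
variant	wildtype
het_weight	5
p_G1	0.9
events_per_cell_mean	1
allow_sister	FALSE
ha_dta_censoring	FALSE
n_cells	250
seed	50625
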