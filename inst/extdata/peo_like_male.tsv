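# telofuse count_table v1
# n_cells	250
# n_TFs	260
# sta	27
# dta	233
# y_fusions	117
# y_rings	18
category	ft_count
A	139
XL	19
XR	73
Fourth	172
Y	117
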