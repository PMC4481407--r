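# telofuse count_table v1
# n_cells	250
# n_TFs	260
# sta	27
# dta	233
# y_fusions	97
# y_rings	4
category	ft_count
A	144
XL	18
XR	66
Fourth	195
Y	97
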