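# telofuse count_table v1
# n_cells	250
# n_TFs	260
# sta	27
# dta	233
# y_fusions	54
# y_rings	2
category	ft_count
A	264
XL	32
XR	43
Fourth	127
Y	54
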