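chrom_class	n_probes
A	42990
X	1428
Y	33
NA	671
all	45122
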