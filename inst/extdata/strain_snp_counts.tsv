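strain	n_snps	n_strain_specific
Songpu mirror carp	8058251	2434141
Yellow River carp	11412638	3674888
Heilongjiang River carp	8688799	2337049
Oujiang color carp	7123672	2209060
Hebao carp	9955915	3156062
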