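accession	raw_gb	mapped_gb	mapping_rate_pct	coverage_rate_pct	depth
Songpu carp 1	11.71	9.90	84.54	89.32	5.84
Songpu carp 2	12.39	10.40	83.93	89.09	6.14
Songpu carp 3	12.66	10.64	84.10	89.35	6.28
Songpu carp 4	11.45	9.62	84.02	88.58	5.68
Yellow River carp 1	10.40	8.30	79.87	86.62	4.90
Yellow River carp 2	10.43	8.33	79.84	87.04	4.91
Yellow River carp 3	11.92	9.08	76.16	87.19	5.36
Yellow River carp 4	14.01	11.11	79.31	89.18	6.56
Heilongjiang River carp 1	13.40	9.21	68.75	86.73	5.44
Heilongjiang River carp 2	16.13	12.25	75.93	89.72	7.23
Heilongjiang River carp 3	15.22	9.46	62.20	87.49	5.58
Hebao carp 1	9.86	7.92	80.32	85.60	4.67
Hebao carp 2	13.63	9.53	69.90	85.63	5.62
Hebao carp 3	13.07	10.36	79.23	88.28	6.11
Hebao carp 4	12.54	10.21	81.44	88.11	6.03
Oujiang color carp 1	11.98	9.65	80.52	87.00	5.69
Oujiang color carp 2	11.39	8.23	72.27	85.65	4.86
Oujiang color carp 3	10.66	8.26	77.48	85.63	4.87
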