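perf_class	carpio_pct	carpio_snps	carpio_probes	related_pct	related_snps	related_probes
PolyHighResolution	74.06	185150	220615	21.65	54116	60143
NoMinorHom	1.68	4202	7173	2.70	6748	8772
MonoHighResolution	0.07	180	315	0.04	88	126
CallRateBelowThreshold	13.50	33742	58146	9.59	23981	32564
OTV	1.15	3610	3610	4.38	10941	20424
Other	9.54	23844	26734	61.65	154126	194564
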