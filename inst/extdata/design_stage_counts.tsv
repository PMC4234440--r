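category	original	runs	gc	uniqueness	proximity	pre_screen	probe_qc	final
nonsyn	47137	32489	32315	25211	11813	9669	8204	8204
utr3	19639	13734	12758	11314	5340	3819	3616	3616
utr5	8145	6488	6420	5042	2516	1864	1603	1603
transcript_other	670325	629039	586832	475850	220137	155437	140879	133603
strain_shared	809662	745423	660045	532121	213189	168216	157579	100974
strain_specific	13811200	12004400	10008670	7401099	3266265	39810	35831	2000
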