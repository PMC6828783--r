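library	raw_reads	clean_reads	trimmed_17_30	mapped	annotated
juvenile	20031228	19499693	18099382	17391597	6159000
subadult	18722856	18300832	17093022	16539316	2505931
adult	19245107	18574516	17280988	16443140	6037898
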