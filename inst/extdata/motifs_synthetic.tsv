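# synthetic example TF->motif table (gene ids follow the simulated id scheme)
tf_gene_id	pattern
g00587	TTTSSCGC
g02867	CCAAT
g01795	GGGCGG
g04167	TGASTCA
g00684	TGACGTCA
g02038	CACGTG
g04853	GGGRNYYYCC
g04794	RRRCWWGYYY
g00307	CCWWWWWWGG
g02360	GGAWR
g02662	TTGCGCAA
g00767	RTAAAYA
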