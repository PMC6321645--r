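chrom	D_SPECIFIC	HOMOEOLOGOUS	UNCLASSIFIED
1D	1674	29307	11760
2D	2295	33822	13975
3D	1611	31932	15532
4D	1698	28781	11776
5D	2936	34961	14336
6D	3730	24534	10966
7D	3983	28593	11606
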