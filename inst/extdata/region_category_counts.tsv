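category	count
D_SPECIFIC	10
HOMOEOLOGOUS	144
UNCLASSIFIED	54
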