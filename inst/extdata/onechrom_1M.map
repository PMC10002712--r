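# single hypothetical chromosome of length 1 Morgan
# chrom	id	pos_cM
chr1	m1	0
chr1	m2	100
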