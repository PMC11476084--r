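chrom	pos	ref	alt	hgvs_c	hgvs_p	consequence	ptc_pos	filters	revel	spliceai	ac_krgdb	an_krgdb
16	23603151	G	C	c.2014G>C	p.(Glu672Gln)	missense	NA		0.12	NA	60	3444
16	23604932	G	A	c.1194G>A	p.(Val398=)	synonymous	NA		NA	NA	12	3444
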