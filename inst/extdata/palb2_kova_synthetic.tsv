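chrom	pos	ref	alt	hgvs_c	hgvs_p	consequence	ptc_pos	filters	revel	spliceai	ac_kova	an_kova
16	23600274	CAA	C	c.2167_2168del	p.(Met723ValfsTer21)	frameshift	2290		NA	NA	1	10610
16	23602055	C	T	c.1048C>T	p.(Gln350Ter)	nonsense	1097		NA	NA	2	10610
16	23603151	G	C	c.2014G>C	p.(Glu672Gln)	missense	NA		0.12	NA	180	10610
16	23603973	CAA	C	c.3267_3268del	p.(Phe1090SerfsTer6)	frameshift	3380		NA	NA	1	10610
16	23604110	T	C	c.2834+2T>C	NA	canonical_splice	NA		NA	0.61	1	10610
16	23604247	CA	C	c.530del	p.(Pro177LeufsTer8)	frameshift	640		NA	NA	1	10610
16	23604384	G	GG	c.757dup	p.(Gln253ProfsTer3)	frameshift	860		NA	NA	1	10610
16	23604521	CA	C	c.1240del	p.(Arg414GlufsTer5)	frameshift	1350		NA	NA	1	10610
16	23604658	G	A	c.3350+1G>A	NA	canonical_splice	NA		NA	0.92	1	10610
16	23604795	CA	C	c.208del	p.(Arg70GlyfsTer6)	frameshift	310		NA	NA	1	10610
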