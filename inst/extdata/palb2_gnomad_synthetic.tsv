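chrom	pos	ref	alt	hgvs_c	hgvs_p	consequence	ptc_pos	filters	revel	spliceai	ac_afr	an_afr	ac_amr	an_amr	ac_asj	an_asj	ac_kor	an_kor	ac_jpn	an_jpn	ac_oea	an_oea	ac_fin	an_fin	ac_nfe	an_nfe	ac_sas	an_sas	ac_oth	an_oth
16	23600137	CA	C	c.1592del	p.(Leu531CysfsTer30)	frameshift	1700		NA	NA	2	16256	3	34592	0	10080	0	3818	0	152	0	14424	30	21648	10	113770	0	30616	1	6140
16	23600274	CAA	C	c.2167_2168del	p.(Met723ValfsTer21)	frameshift	2290		NA	NA	0	16256	10	34592	0	10080	0	3818	0	152	0	14424	0	21648	4	113770	2	30616	0	6140
16	23600411	G	A	c.3113G>A	p.(Trp1038Ter)	nonsense	3162		NA	NA	3	16256	2	34592	0	10080	0	3818	0	152	0	14424	1	21648	8	113770	0	30616	0	6140
16	23600548	CAAAA	C	c.172_175del	p.(Gln60ArgfsTer7)	frameshift	280		NA	NA	0	16256	2	34592	0	10080	0	3818	0	152	0	14424	0	21648	9	113770	2	30616	0	6140
16	23600685	CAA	C	c.509_510del	p.(Arg170IlefsTer14)	frameshift	600		NA	NA	2	16256	2	34592	0	10080	0	3818	0	152	0	14424	0	21648	8	113770	0	30616	0	6140
16	23600822	G	T	c.2968G>T	p.(Glu990Ter)	nonsense	3017		NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	4	14424	0	21648	0	113770	0	30616	0	6140
16	23600959	CAAAA	C	c.1050_1053del	p.(Thr351ArgfsTer4)	frameshift	1160		NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	1	14424	0	21648	0	113770	1	30616	0	6140
16	23601096	CA	C	c.3116del	p.(Asn1039IlefsTer2)	frameshift	3220		NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	0	14424	8	21648	20	113770	0	30616	0	6140
16	23601233	C	T	c.757C>T	p.(Gln253Ter)	nonsense	806		NA	NA	4	16256	0	34592	0	10080	0	3818	0	152	0	14424	0	21648	15	113770	0	30616	0	6140
16	23601370	G	GG	c.3456dup	p.(Gln1153SerfsTer12)	frameshift	3560		NA	NA	0	16256	5	34592	0	10080	0	3818	0	152	0	14424	0	21648	12	113770	0	30616	3	6140
16	23601507	C	T	c.196C>T	p.(Gln66Ter)	nonsense	245		NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	0	14424	0	21648	12	113770	4	30616	0	6140
16	23601644	CA	C	c.2390del	p.(Pro797GlnfsTer2)	frameshift	2500		NA	NA	5	16256	0	34592	1	10080	0	3818	0	152	0	14424	5	21648	0	113770	0	30616	0	6140
16	23601781	C	A	c.3549C>A	p.(Tyr1183Ter)	nonsense	3598		NA	NA	0	16256	4	34592	0	10080	0	3818	0	152	0	14424	0	21648	0	113770	3	30616	4	6140
16	23601918	A	T	c.661A>T	p.(Lys221Ter)	nonsense	710		NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	1	14424	0	21648	0	113770	0	30616	0	6140
16	23602055	C	T	c.1048C>T	p.(Gln350Ter)	nonsense	1097		NA	NA	0	16256	0	34592	0	10080	1	3818	0	152	0	14424	0	21648	0	113770	0	30616	0	6140
16	23602192	C	T	c.2257C>T	p.(Arg753Ter)	nonsense	2306		NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	0	14424	0	21648	7	113770	0	30616	0	6140
16	23602329	G	A	c.3201+1G>A	NA	canonical_splice	NA		NA	0.84	0	16256	1	34592	1	10080	0	3818	0	152	0	14424	0	21648	0	113770	2	30616	0	6140
16	23602466	CA	C	c.93del	p.(Ile32SerfsTer8)	frameshift	190		NA	NA	0	16256	0	34592	0	10080	1	3818	0	152	0	14424	0	21648	0	113770	0	30616	0	6140
16	23602603	C	T	c.1684C>T	p.(Gln562Ter)	nonsense	1733		NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	0	14424	0	21648	0	113770	1	30616	0	6140
16	23602740	T	G	c.2816T>G	p.(Leu939Trp)	missense	NA		0.52	NA	1	16256	6	34592	0	10080	0	3818	0	152	0	14424	0	21648	20	113770	0	30616	0	6140
16	23602877	T	C	c.1010T>C	p.(Leu337Ser)	missense	NA		0.47	NA	0	16256	4	34592	0	10080	0	3818	0	152	0	14424	0	21648	12	113770	0	30616	2	6140
16	23603014	T	A	c.3428T>A	p.(Leu1143His)	missense	NA		0.55	NA	0	16256	0	34592	0	10080	0	3818	0	152	8	14424	0	21648	0	113770	0	30616	0	6140
16	23603151	G	C	c.2014G>C	p.(Glu672Gln)	missense	NA		0.12	NA	120	16256	260	34592	40	10080	15	3818	1	152	60	14424	110	21648	2000	113770	150	30616	30	6140
16	23603288	T	C	c.212-5T>C	NA	splice_region	NA		NA	0.05	0	16256	0	34592	0	10080	0	3818	0	152	0	14424	0	21648	30	113770	0	30616	0	6140
16	23603425	C	T	c.2589C>T	p.(Ala863=)	synonymous	NA		NA	NA	0	16256	15	34592	0	10080	0	3818	0	152	0	14424	0	21648	0	113770	0	30616	0	6140
16	23603562	C	T	c.448C>T	p.(Gln150Ter)	nonsense	497	RF	NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	0	14424	2	21648	5	113770	0	30616	0	6140
16	23603699	T	C	c.2T>C	p.(Met1?)	initiation_codon	NA	AC0	NA	NA	0	16256	0	34592	0	10080	0	3818	0	152	0	14424	0	21648	0	113770	0	30616	0	6140
16	23603836	T	G	c.3300T>G	p.(Phe1100Cys)	missense	NA		0.97	NA	0	16256	0	34592	0	10080	0	3818	0	152	0	14424	0	21648	600	113770	0	30616	0	6140
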