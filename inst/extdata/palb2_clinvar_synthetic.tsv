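chrom	pos	ref	alt	assertion
16	23600137	CA	C	Pathogenic
16	23600274	CAA	C	Pathogenic
16	23600411	G	A	Pathogenic
16	23600548	CAAAA	C	Pathogenic
16	23600685	CAA	C	Pathogenic
16	23600822	G	T	Likely_pathogenic
16	23600959	CAAAA	C	Likely_pathogenic
16	23601096	CA	C	Pathogenic
16	23601233	C	T	Pathogenic
16	23601370	G	GG	Pathogenic
16	23601507	C	T	Pathogenic
16	23601644	CA	C	Pathogenic
16	23601781	C	A	Likely_pathogenic
16	23601918	A	T	Likely_pathogenic
16	23602055	C	T	Pathogenic
16	23603151	G	C	Benign
16	23603288	T	C	Uncertain_significance
16	23603562	C	T	Pathogenic
16	23603699	T	C	Likely_pathogenic
16	23603836	T	G	Conflicting
16	23603973	CAA	C	Pathogenic
16	23604110	T	C	Likely_pathogenic
16	23604247	CA	C	Likely_pathogenic
16	23604384	G	GG	Likely_pathogenic
16	23604521	CA	C	Likely_pathogenic
16	23604658	G	A	Likely_pathogenic
16	23604795	CA	C	Likely_pathogenic
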