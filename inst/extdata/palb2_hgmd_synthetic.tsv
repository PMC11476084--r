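chrom	pos	ref	alt	assertion
16	23600137	CA	C	DM
16	23600274	CAA	C	DM
16	23600411	G	A	DM
16	23600548	CAAAA	C	DM
16	23600685	CAA	C	DM
16	23600822	G	T	DM
16	23600959	CAAAA	C	DM
16	23601096	CA	C	DM
16	23601233	C	T	DM
16	23601370	G	GG	DM
16	23601507	C	T	DM
16	23601644	CA	C	DM
16	23601781	C	A	DM
16	23601918	A	T	DM
16	23602192	C	T	DM
16	23602329	G	A	DM
16	23602740	T	G	DM
16	23602877	T	C	DM
16	23603014	T	A	DM
16	23603288	T	C	DP
16	23603425	C	T	DM?
16	23603562	C	T	DM
16	23603973	CAA	C	DM
16	23604247	CA	C	DM
16	23604384	G	GG	DM
16	23604521	CA	C	DM
16	23604658	G	A	DM
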