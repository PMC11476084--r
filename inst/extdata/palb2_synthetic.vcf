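##fileformat=VCFv4.2
##INFO=<ID=AC_eas,Number=A,Type=Integer,Description="East Asian allele count">
##INFO=<ID=AN_eas,Number=1,Type=Integer,Description="East Asian allele number">
##INFO=<ID=AC_nfe,Number=A,Type=Integer,Description="Non-Finnish European allele count">
##INFO=<ID=AN_nfe,Number=1,Type=Integer,Description="Non-Finnish European allele number">
##INFO=<ID=CONSEQ,Number=A,Type=String,Description="Molecular consequence">
##INFO=<ID=PTC_POS,Number=A,Type=Integer,Description="PTC transcript position">
##INFO=<ID=REVEL,Number=A,Type=Float,Description="REVEL score">
##INFO=<ID=SPLICEAI,Number=A,Type=Float,Description="SpliceAI max delta score">
##INFO=<ID=HGVSC,Number=A,Type=String,Description="Coding HGVS">
##FILTER=<ID=RF,Description="Random forest filter">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
16	23614000	.	C	T	.	PASS	AC_eas=3;AN_eas=18394;AC_nfe=1;AN_nfe=113770;CONSEQ=nonsense;PTC_POS=1097;HGVSC=c.1048C>T
16	23614500	.	G	A,C	.	PASS	AC_eas=2,1;AN_eas=18394;AC_nfe=5,0;AN_nfe=113770;CONSEQ=missense,missense;REVEL=0.41,0.88;HGVSC=c.2014G>A,c.2014G>C
16	23615000	.	TA	T	.	RF	AC_eas=4;AN_eas=18394;AC_nfe=0;AN_nfe=113770;CONSEQ=frameshift;PTC_POS=2290;HGVSC=c.2167del
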