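##fileformat=VCFv4.2
##source=toy
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	100	rs1	A	G	50	PASS	DP=10
chr1	100	sv1	ACGT	<DEL>	.	PASS	END=5000;SVTYPE=DEL
chr2	7	.	AT	A,ATT	12.5	q10	DP=3
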