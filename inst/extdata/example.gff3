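##gff-version 3
# a comment
chr1	rangekit	gene	1000	2000	.	+	.	ID=gene1;Name=abc
chr1	rangekit	exon	1000	1300	0.9	+	0	Parent=gene1
##FASTA
>chr1
ACGTACGT
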