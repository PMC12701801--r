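chrom_1	start_1	end_1	name_1	chrom_2	start_2	end_2	name_2
chr1	10	100	a1	chr1	50	95	b1
chr1	90	200	a2	chr1	50	95	b1
chr1	90	200	a2	chr1	150	160	b2
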