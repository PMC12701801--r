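chr1	10	100	a1
chr1	90	200	a2
chr2	0	50	a3
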