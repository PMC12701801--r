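chr1	50	95	b1
chr1	150	160	b2
chr2	100	200	b3
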