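track name="toy" description="demo"
# comment line
chr1	0	100	feat1	960	+
chr1	150	200	feat2	500	-
chr2	5	25	feat3	0	+
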