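class	L
intron	3000
intergenic	3200
synonymous	439.333333333333
nonsynonymous	1360.66666666667
exome	1800
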