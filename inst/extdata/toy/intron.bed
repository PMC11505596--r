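chr1	6300	6800
chr1	253700	254200
chr2	6300	6800
chr2	253700	254200
chr3	6300	6800
chr3	253700	254200
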