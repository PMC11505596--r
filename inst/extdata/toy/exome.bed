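chr1	6000	6300
chr1	253400	253700
chr2	6000	6300
chr2	253400	253700
chr3	6000	6300
chr3	253400	253700
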