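chr1	299200	300000
chr2	299200	300000
chr3	299200	300000
chr4	299200	300000
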