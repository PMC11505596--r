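gene_id	n_sites	s_sites	cds_len	intron_len
g0001	224.333333333333	75.6666666666667	300	500
g0002	228.333333333333	71.6666666666667	300	500
g0003	224.333333333333	75.6666666666667	300	500
g0004	225.333333333333	74.6666666666667	300	500
g0005	229.333333333333	70.6666666666667	300	500
g0006	229	71	300	500
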