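gene_id	chrom	start0	end0	feature
g0001	chr1	6000	6300	cds
g0002	chr1	253400	253700	cds
g0003	chr2	6000	6300	cds
g0004	chr2	253400	253700	cds
g0005	chr3	6000	6300	cds
g0006	chr3	253400	253700	cds
g0001	chr1	6300	6800	intron
g0002	chr1	253700	254200	intron
g0003	chr2	6300	6800	intron
g0004	chr2	253700	254200	intron
g0005	chr3	6300	6800	intron
g0006	chr3	253700	254200	intron
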