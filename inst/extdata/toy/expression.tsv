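gene_id	expression
g0001	6.6676
g0002	6.5073
g0003	6.3329
g0004	5.9654
g0005	5.9851
g0006	5.9208
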