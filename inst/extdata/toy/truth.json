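{"seed":42,"s":[0.00625,0.00625,0.00625,0.00625,0.00625,0.00625],"gamma_large":[-10,-10,-10,-10,-10,-10],"gamma_small":[-2.5,-2.5,-2.5,-2.5,-2.5,-2.5],"theta_large":0.0128,"theta_small":0.0032,"delta_nonsyn_intron":0.678162261431186}
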