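# Reference illustration configuration for the apparent-viscosity curve: eta_c = 3.3, a_star_um = 1.2, three marginal viscosity fractions, diameters 10-1000 um.
eta_c,a_star_um,alpha,D_min_um,D_max_um
3.3,1.2,0.05,10,1000
3.3,1.2,0.10,10,1000
3.3,1.2,0.15,10,1000
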