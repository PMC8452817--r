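# Marginal-layer thickness in rigid 30 um tubes, human blood; measurements reported by Maeda and co-workers. Model inputs a_star_um = 1.2, alpha = 0.1; eta_c estimated from phi via Charm-Kurland. thickness_theor_um transcribes the published model values as printed.
phi,eta_ck,thickness_meas_um,thickness_meas_err_um,thickness_theor_um,D_um,a_star_um,alpha
0.08,1.18,3.9,1.0,2.7,30,1.2,0.1
0.16,1.34,3.1,0.5,2.7,30,1.2,0.1
0.30,1.61,2.3,0.8,2.6,30,1.2,0.1
0.45,2.05,1.6,0.5,2.6,30,1.2,0.1
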