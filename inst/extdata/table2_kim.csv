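# Marginal-layer thickness in 30-73 um tubes, rat blood; measurements reported by Kim and co-workers. Model inputs a_star_um = 0.8 (rat RBCs are 25-30% smaller than human), alpha = 0.1; eta_c estimated from phi via Charm-Kurland. thickness_theor_um transcribes the published model values as printed.
phi,eta_ck,D_um,thickness_meas_um,thickness_meas_err_um,thickness_theor_um,a_star_um,alpha
0.42,1.94,72.3,2.7,0.5,3.4,0.8,0.1
0.42,1.94,49.2,3.1,0.6,2.9,0.8,0.1
0.42,1.94,45.3,2.3,0.4,2.8,0.8,0.1
0.42,1.94,30.8,2.1,0.4,2.4,0.8,0.1
0.41,1.90,71.1,3.2,0.7,3.2,0.8,0.1
0.41,1.90,60.2,2.2,0.4,3.0,0.8,0.1
0.41,1.90,54.2,2.9,0.6,2.9,0.8,0.1
0.41,1.90,51.7,2.3,0.4,2.8,0.8,0.1
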