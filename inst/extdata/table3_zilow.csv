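# Core-annulus parameters fitted to the adult/infant blood viscometry data of Zilow and Linderkamp, at three hematocrit levels.
subject,phi,eta_c,a_star_um,alpha
Infant,0.6,6.4,1.2,0.10
Adult,0.2,1.7,1.3,0.09
Adult,0.4,3.5,1.2,0.11
Adult,0.6,6.0,1.0,0.14
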