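molecular_mass,stokes_radius,role
92,0.18,tracer
570,0.51,standard
1920,1.05,standard
3460,1.48,standard
9630,2.71,standard
17300,3.82,standard
27500,5.01,standard
62300,8.11,standard
96000,10.46,standard
139000,13.00,standard
319000,21.19,standard
524000,28.37,standard
925000,39.63,standard
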