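adsorbent,v0_ml,vt_ml,inner_diameter_cm,length_cm
CG161c,1.06,2.30,0.46,15
CG300m,1.14,2.25,0.46,15
HAC,1.13,2.31,0.46,15
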