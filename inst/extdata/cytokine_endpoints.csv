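analyte,condition,time_h,concentration_pg_ml,sd_pg_ml,n
TNF-a,control,6,3102,533,3
TNF-a,CG161c,6,177,7,3
TNF-a,CG300m,6,1131,16,3
TNF-a,HAC,6,1445,212,3
IL-1b,control,6,830,190,3
IL-1b,CG161c,6,7,1,3
IL-1b,CG300m,6,10,1,3
IL-1b,HAC,6,45,3,3
IL-6,control,6,24273,13446,3
IL-6,CG161c,6,59,18,3
IL-6,CG300m,6,65,3,3
IL-6,HAC,6,2587,1254,3
IL-8,control,6,4837,2300,3
IL-8,CG161c,6,8,7,3
IL-8,CG300m,6,10,6,3
IL-8,HAC,6,60,52,3
IL-10,control,6,51,9,3
IL-10,CG161c,6,<2,,3
IL-10,CG300m,6,<2,,3
IL-10,HAC,6,7,4,3
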