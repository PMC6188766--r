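family,depth_cm,metric,shift,magnitude_cm,dose_gyeq,published_pct_change,consistent
cylinder,6.5,D_mean,none,0,24.31,NA,TRUE
cylinder,6.5,D_mean,lateral,1,23.95,1.48,TRUE
cylinder,6.5,D_mean,lateral,2,23.02,5.31,TRUE
cylinder,6.5,D_mean,lateral,3,21.56,11.31,TRUE
cylinder,6.5,D_mean,outward,1,22.19,4.72,FALSE
cylinder,6.5,D_mean,outward,2,21.43,11.85,TRUE
cylinder,6.5,D_mean,outward,3,20.21,16.87,TRUE
cylinder,6.5,D_80pct,none,0,20.00,NA,TRUE
cylinder,6.5,D_80pct,lateral,1,19.52,NA,TRUE
cylinder,6.5,D_80pct,lateral,2,18.50,NA,TRUE
cylinder,6.5,D_80pct,lateral,3,17.67,NA,TRUE
cylinder,6.5,D_80pct,outward,1,18.25,NA,TRUE
cylinder,6.5,D_80pct,outward,2,17.75,NA,TRUE
cylinder,6.5,D_80pct,outward,3,16.73,NA,TRUE
cylinder,2.5,D_mean,none,0,20.69,NA,TRUE
cylinder,2.5,D_mean,lateral,1,20.51,0.87,TRUE
cylinder,2.5,D_mean,lateral,2,19.84,4.11,TRUE
cylinder,2.5,D_mean,lateral,3,18.75,9.38,TRUE
cylinder,2.5,D_mean,outward,1,19.81,4.25,TRUE
cylinder,2.5,D_mean,outward,2,18.43,10.92,TRUE
cylinder,2.5,D_mean,outward,3,17.52,15.32,TRUE
cylinder,2.5,D_80pct,none,0,20.00,NA,TRUE
cylinder,2.5,D_80pct,lateral,1,19.85,NA,TRUE
cylinder,2.5,D_80pct,lateral,2,18.66,NA,TRUE
cylinder,2.5,D_80pct,lateral,3,17.67,NA,TRUE
cylinder,2.5,D_80pct,outward,1,18.50,NA,TRUE
cylinder,2.5,D_80pct,outward,2,17.79,NA,TRUE
cylinder,2.5,D_80pct,outward,3,16.96,NA,TRUE
head,6.5,D_mean,none,0,24.45,NA,TRUE
head,6.5,D_mean,lateral,1,24.10,1.43,TRUE
head,6.5,D_mean,lateral,2,23.13,5.52,FALSE
head,6.5,D_mean,lateral,3,21.73,11.12,TRUE
head,6.5,D_mean,outward,1,23.30,4.70,TRUE
head,6.5,D_mean,outward,2,21.84,10.67,TRUE
head,6.5,D_mean,outward,3,20.74,15.17,TRUE
head,6.5,D_80pct,none,0,20.00,NA,TRUE
head,6.5,D_80pct,lateral,1,19.92,NA,TRUE
head,6.5,D_80pct,lateral,2,18.72,NA,TRUE
head,6.5,D_80pct,lateral,3,17.84,NA,TRUE
head,6.5,D_80pct,outward,1,19.33,NA,TRUE
head,6.5,D_80pct,outward,2,18.34,NA,TRUE
head,6.5,D_80pct,outward,3,17.15,NA,TRUE
head,2.5,D_mean,none,0,20.68,NA,TRUE
head,2.5,D_mean,lateral,1,20.55,0.63,TRUE
head,2.5,D_mean,lateral,2,19.93,3.63,TRUE
head,2.5,D_mean,lateral,3,18.85,8.85,TRUE
head,2.5,D_mean,outward,1,19.70,4.74,TRUE
head,2.5,D_mean,outward,2,18.92,8.51,TRUE
head,2.5,D_mean,outward,3,18.08,12.57,TRUE
head,2.5,D_80pct,none,0,20.00,NA,TRUE
head,2.5,D_80pct,lateral,1,19.89,NA,TRUE
head,2.5,D_80pct,lateral,2,18.74,NA,TRUE
head,2.5,D_80pct,lateral,3,17.83,NA,TRUE
head,2.5,D_80pct,outward,1,19.11,NA,TRUE
head,2.5,D_80pct,outward,2,18.28,NA,TRUE
head,2.5,D_80pct,outward,3,17.47,NA,TRUE
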