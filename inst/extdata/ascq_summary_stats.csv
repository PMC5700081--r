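comparison,dimension,design,n1,n2,t,bf10_printed,d_printed
control,intensity,paired,12,NA,4.185,28.09,1.208
control,patterns,paired,12,NA,13.7,389022,3.955
control,imagery,paired,12,NA,9.803,18187,2.83
control,mood,paired,12,NA,1.685,0.866,0.486
control,ego,paired,12,NA,2.669,3.162,0.77
control,arousal,paired,12,NA,4.391,37.58,1.268
control,strange,paired,12,NA,7.44,1721,2.148
control,vivid,paired,12,NA,5.254,122.1,1.1517
control,time,paired,12,NA,0.849,0.39,0.245
control,space,paired,12,NA,7.005,1057,2.022
control,muddle,paired,12,NA,3.183,6.613,0.919
control,merge,paired,12,NA,-1.146,0.494,-0.331
control,control,paired,12,NA,2.218,1.697,0.64
control,spirit,paired,12,NA,2.715,3.375,0.784
control,peace,paired,12,NA,2.149,1.547,0.62
control,float,paired,12,NA,1.008,0.44,0.291
control,past,paired,12,NA,-1.133,0.488,-0.327
psilocybin,intensity,independent,12,15,-2.55,3.404,-1.004
psilocybin,patterns,independent,12,15,2.364,2.545,0.916
psilocybin,ego,independent,12,15,1.335,0.69,0.517
psilocybin,strange,independent,12,15,2.467,2.993,0.955
psilocybin,vivid,independent,12,15,0.723,0.437,0.28
psilocybin,time,independent,12,15,-0.82,0.461,-0.317
psilocybin,space,independent,12,15,0.747,0.442,0.289
psilocybin,muddle,independent,12,15,0.428,0.385,0.166
psilocybin,merge,independent,12,15,0.364,0.378,0.141
psilocybin,control,independent,12,15,2.056,1.617,0.796
psilocybin,spirit,independent,12,15,2.144,1.83,0.83
psilocybin,peace,independent,12,15,0.688,0.429,0.267
psilocybin,float,independent,12,15,-1.631,0.945,-0.633
psilocybin,past,independent,12,15,-0.171,0.363,-0.067
exp2,presence,paired,21,NA,3.705,26.960,0.808
exp2,attention,paired,21,NA,2.822,4.830,0.616
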