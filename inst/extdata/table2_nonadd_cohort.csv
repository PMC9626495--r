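sample_id,source,age,gender,group,validation,comorbidity,ln_a_over_n
ND27760,Coriell,55,F,nonADD,Parkinson's disease (PD),0,4.6
GM02173,Coriell,52,F,nonADD,Huntington's disease (HD),0,4.77
GM04715,Coriell,40,M,nonADD,Huntington's disease (HD),0,4.93
GM05031,Coriell,60,M,nonADD,Huntington's disease (HD),0,5.1
AG08395,Coriell,85,F,nonADD,Parkinson's disease (PD),0,5.15
GM00305,Coriell,56,F,nonADD,Huntington's disease (HD),0,5.36
GM02165,Coriell,67,M,nonADD,Huntington's disease (HD),0,5.4
GM04210,Coriell,59,M,nonADD,Huntington's disease (HD),0,5.58
GM05030,Coriell,56,M,nonADD,Huntington's disease (HD),0,5.61
GM04222,Coriell,59,M,nonADD,Huntington's disease (HD),0,5.89
GM02167,Coriell,59,F,nonADD,Huntington's disease (HD),0,5.91
ND34265,Coriell,62,M,nonADD,Parkinson's disease (PD),0,6.01
GM04476,Coriell,57,M,nonADD,Huntington's disease (HD),0,6.04
GM02038,Coriell,22,M,nonADD,Schizophrenia,0,6.18
GM04198,Coriell,63,F,nonADD,Huntington's disease (HD),0,6.48
ND31618,Coriell,58,F,nonADD,Parkinson's disease (PD),0,6.75
AG06274,Coriell,65,F,nonADD,Huntington's disease (HD),0,6.77
564,NA,67,F,nonADD,Corticobasal degeneration (CBD),0,5.8
574,CRI,90,F,nonADD,Parkinson's disease (PD),0,5.66
586,CRI,69,M,nonADD,Frontotemporal lobar degeneration with TDP-43-positive inclusions (FTLD-TDP),0,6.5
572,CRI,60,F,nonADD,"Parkinson's disease (PD), Lewy body disease",0,6.28
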