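sample_id,source,age,gender,group,validation,comorbidity,ln_a_over_n
538,UTSW,79,M,AD,Autopsy,0,8.39
539,UTSW,77,M,AD,Autopsy,0,7.1
557,UTSW,78,M,AD,Autopsy,1,7.55
AG05770,Coriell,70,M,AD,Autopsy,0,8.11
AG08245,Coriell,75,M,AD,Autopsy,2,9.78
AG08527,Coriell,61,M,AD,Autopsy,1,7.57
AG06840,Coriell,56,M,AD,Genetic,0,9.2
AG04159,Coriell,52,F,AD,Genetic,0,10.67
AG06844,Coriell,59,M,AD,Genetic,0,9.79
AG10788,Coriell,87,Unknown,AD,Genetic,0,8.08
AG06869,Coriell,60,F,AD,Autopsy,0,8.03
AG11368,Coriell,77,M,AD,Autopsy,0,7.16
AG05810,Coriell,79,F,AD,Autopsy,0,10.49
550,UTSW,72,M,AD,Autopsy,0,9.54
588,CRI,78,M,AD,Autopsy,2,7.85
658,CRI,88,F,AD,Autopsy,1,7.17
568,CRI,87,F,AD,Autopsy,2,8.92
575,CRI,55,F,AD,Autopsy,2,8.92
589,CRI,80,F,AD,Autopsy,4,7.97
578,CRI,70,M,AD,Autopsy,5,7.91
563,CRI,81,F,AD,Autopsy,NA,7.86
652,CRI,86,F,AD,Autopsy,2,7.85
599,WHM,79,M,AD,Autopsy,1,7.71
587,CRI,85,F,AD,Autopsy,1,7.61
590,CRI,90,F,AD,Autopsy,2,7.26
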