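sample_id,source,age,gender,group,validation,comorbidity,ln_a_over_n
AG09977,Coriell,63,F,AHC,Healthy control,0,4.21
AG11730,Coriell,84,M,AHC,Healthy control,0,4.36
AG12927,Coriell,66,F,AHC,Healthy control,0,4.36
AG12998,Coriell,65,M,AHC,Healthy control,0,4.46
AG04146,Coriell,57,M,AHC,Healthy control,0,4.75
AG07123,Coriell,62,M,AHC,Healthy control,0,5.05
AG13358,Coriell,72,F,AHC,Healthy control,0,5.08
AG04461,Coriell,66,M,AHC,Healthy control,0,5.09
AG07714,Coriell,56,F,AHC,Healthy control,0,5.22
AG12438,Coriell,77,M,AHC,Healthy control,0,5.55
AG05840,Coriell,56,F,AHC,Healthy control,0,6.66
37,Clinic,65,F,AHC,Healthy control,0,5.81
39,Clinic,65,F,AHC,Healthy control,0,7.13
50,Clinic,61,M,AHC,Healthy control,0,6.70
51,Clinic,55,M,AHC,Healthy control,0,4.71
19,Clinic,33,M,AHC,Healthy control,0,6.71
25,Clinic,39,M,AHC,Healthy control,0,6.05
29,Clinic,21,M,AHC,Healthy control,0,6.62
32,Clinic,23,M,AHC,Healthy control,0,6.69
36,Clinic,46,M,AHC,Healthy control,0,6.41
44,Clinic,50,F,AHC,Healthy control,0,6.75
73,Clinic,20,F,AHC,Healthy control,0,6.24
77,Clinic,18,M,AHC,Healthy control,0,5.81
78,Clinic,45,F,AHC,Healthy control,0,6.23
82,Clinic,45,F,AHC,Healthy control,0,6.52
83,Clinic,20,M,AHC,Healthy control,0,6.58
84,Clinic,21,M,AHC,Healthy control,0,6.45
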