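pt,group,n_reports,ic,ror,prr,ror_low,ror_high,prr_low,prr_high,ic_low,ic_high
Breast enlargement,reproductive,77,1.16,1.7,1.7,1.47,1.92,1.47,1.92,0.38,1.93
Breast tenderness,reproductive,901,12.38,3.7,3.68,3.62,3.77,3.6,3.75,12.12,12.63
Dysmenorrhea,reproductive,822,9.72,3.46,3.44,3.38,3.53,3.36,3.51,9.46,9.97
Ectopic pregnancy,reproductive,61,0.5,1.3,1.3,1.04,1.55,1.04,1.55,-0.35,1.35
Menorrhagia,reproductive,541,1.86,1.89,1.88,1.8,1.97,1.79,1.96,1.57,2.16
Menstruation delayed,reproductive,1791,28.24,4.53,4.49,4.46,4.59,4.43,4.54,28.03,28.44
Metrorrhagia,reproductive,899,4.2,2.63,2.61,2.56,2.69,2.54,2.67,3.96,4.43
Nipple disorder,reproductive,141,4.8,2.83,2.83,2.65,3,2.65,3,4.2,5.39
Pregnancy after post coital contraception,reproductive,942,129.22,6.51,6.49,6.34,6.67,6.32,6.65,128.67,129.76
Premenstrual syndrome,reproductive,35,0.52,1.5,1.5,1.16,1.83,1.16,1.83,-0.61,1.65
Diarrhoea,miscellaneous,NA,-0.26,-1.36,-1.34,NA,NA,NA,NA,NA,NA
Dysuria,miscellaneous,NA,-0.37,-0.27,-0.27,NA,NA,NA,NA,NA,NA
Fungal infection,miscellaneous,NA,-0.25,0.08,0.08,NA,NA,NA,NA,NA,NA
Muscle spasm,miscellaneous,NA,-0.05,-0.18,-0.18,NA,NA,NA,NA,NA,NA
Pollakiuria,miscellaneous,NA,-0.13,0.16,0.16,NA,NA,NA,NA,NA,NA
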