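analyte,role,parent,C0,alpha,se_alpha,r_corr,beta,se_beta,D0,se_D0,k,se_k
tetracycline,antibiotic,,100,1.28,0.16,0.99,,,,,,
461.1549,product,tetracycline,,,,,0.65,0.08,0.98,0.12,0.14,0.02
400.1024,product,tetracycline,,,,,1.44,0.18,0.09,0.01,0.10,0.01
384.1074,product,tetracycline,,,,,1.20,0.15,0.09,0.01,0.07,0.01
416.1334,product,tetracycline,,,,,0.98,0.12,0.53,0.07,0.09,0.01
437.1205,product,tetracycline,,,,,0.10,0.01,1.04,0.13,0.015,0.002
ampicillin,antibiotic,,100,2.38,0.24,0.98,,,,,,
366.1111,product,ampicillin,,,,,3.38,0.34,2.33,0.24,0.12,0.01
368.1274,product,ampicillin,,,,,32.12,3.25,0.07,0.01,0.28,0.03
amoxicillin,antibiotic,,100,2.18,0.84,0.99,,,,,,
365.0801,product,amoxicillin,,,,,3.29,1.27,6.01,2.32,0.72,0.26
382.1066,product,amoxicillin,,,,,3.34,1.30,3.08,1.19,0.76,0.29
benzylpenicillin,antibiotic,,100,2.51,0.12,0.99,,,,,,
351.1007,product,benzylpenicillin,,,,,4.97,0.23,3.86,0.18,0.54,0.02
353.1168,product,benzylpenicillin,,,,,22.77,1.05,0.0022,0.0001,1.60,0.07
streptomycin,antibiotic,,100,1.02,0.50,0.99,,,,,,
302.1233,product,streptomycin,,,,,1.12,0.56,2.39,1.19,0.96,0.48
290.1232,product,streptomycin,,,,,3.28,1.65,0.05,0.03,0.74,0.37
288.1077,product,streptomycin,,,,,0.68,0.34,0.05,0.03,0.38,0.19
doxycycline,antibiotic,,100,0.56,0.04,0.89,,,,,,
chloramphenicol,antibiotic,,100,1.49,0.08,0.98,,,,,,
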