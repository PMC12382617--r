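name,parent,formula,rt_min,dose_kGy,mz,mass_accuracy_ppm
DP-TC-460,tetracycline,C22H25N2O9,6.51;7.31,1,461.1549,-1.31
DP-TC-399,tetracycline,C20H18NO8,9.33,1,400.1024,-0.77
DP-TC-383,tetracycline,C20H18NO7,9.68,1,384.1074,-0.37
DP-TC-415,tetracycline,C21H22NO8,7.74,1,416.1334,-1.44
DP-TC-436,tetracycline,C19H21N2O10,7.92,3,437.1205,0.31
DP-AMO-364,amoxicillin,C16H17N2SO6,2.81,0.1,365.0801,0.07
DP-AMO-381,amoxicillin,C16H20N3SO6,1.97,0.1,382.1066,-0.33
DP-AMP-365,ampicillin,C16H20N3SO5,5.12,0.1,366.1111,-0.37
DP-AMP-367,ampicillin,C16H22N3SO5,5.60,0.1,368.1274,0.82
DP-PENG-350,benzylpenicillin,C16H19N2SO5,8.16;8.40;8.83,0.1,351.1007,-0.34
DP-PENG-352,benzylpenicillin,C16H21N2SO5,7.83,0.1,353.1168,0.54
DP-PENG-308,benzylpenicillin,C15H21N2SO3,7.83,0.1,309.1276,-0.2
DP-STR-301,streptomycin,C13H20O7N,1.31,0.1,302.1233,-0.56
DP-STR-289,streptomycin,C12H20O7N,1.82,0.1,290.1232,-0.79
DP-STR-287,streptomycin,C12H18O7N,3.07,0.1,288.1077,-0.18
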