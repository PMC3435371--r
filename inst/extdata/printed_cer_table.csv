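source_table,group,age_stratum,n_cases,le,qale_partial,qale_poor,cost_insurer,cost_oop,cer_partial_printed,cer_poor_printed,total_printed
table2,Overall,all,21316,3.26,0.93,0.47,32873,30450,68089,134730,NA
table2,Cancer,all,5367,1.49,0.46,0.20,15835,13931,64708,148829,NA
table2,Renal failure,all,2032,1.32,0.40,0.18,24253,12237,91224,202720,NA
table2,Liver cirrhosis,all,1478,3.50,1.15,0.50,19652,32568,45409,104440,NA
table2,Degenerative nervous diseases,all,378,4.08,1.28,0.56,78622,36898,90250,206286,NA
table2,Parkinson's disease,all,341,2.01,0.59,0.26,44708,17461,105371,239110,NA
table2,Stroke,all,6765,3.32,1.05,0.46,42452,29932,68938,157358,NA
table2,Stroke,<64,1955,5.24,1.60,0.72,54686,47487,63858,141907,NA
table2,Stroke,65-74,1818,2.93,1.14,0.40,43350,26120,60939,173676,NA
table2,Stroke,75-84,2176,2.03,0.61,0.27,40099,17978,95209,215101,NA
table2,Stroke,>85,816,1.42,0.49,0.21,30056,12486,86820,202581,NA
table2,Intracranial or spinal injury,all,4955,6.19,2.04,0.89,43090,56806,48969,112242,NA
table2,Intracranial or spinal injury,<64,1949,10.06,3.40,1.47,56872,92951,44065,101920,NA
table2,Intracranial or spinal injury,65-74,1116,3.71,1.18,0.51,38268,33415,60748,140555,NA
table2,Intracranial or spinal injury,75-84,1366,2.64,0.82,0.33,33405,23720,69665,173106,NA
table2,Intracranial or spinal injury,>85,524,1.51,0.52,0.22,30213,13319,83715,197873,NA
table2,Cases with >2 specific diseases,all,4772,2.90,0.93,0.40,32137,26450,62997,146467,NA
table2,Cancer and renal failure,all,165,1.14,0.36,0.16,23236,10778,94482,212585,NA
table2,Cancer and others,all,1609,1.82,0.58,0.26,19773,16849,63141,140853,NA
table2,Renal failure and others,all,743,1.65,0.52,0.23,26698,15484,81119,183400,NA
table3,Heart diseases,<65,616,4.97,1.61,0.70,47230,45463,57574,132419,NA
table3,Septicemia/Shock,<65,919,4.42,1.22,0.64,27797,40663,56115,106969,NA
table3,Urinary tract infections/Shock,<65,197,4.77,1.43,0.62,54799,43487,68731,158525,NA
table3,COPD,<65,1788,5.18,1.66,0.72,59284,46875,63951,147444,NA
table3,Heart diseases,65-74,1074,2.49,0.77,0.34,30948,22496,69408,157189,NA
table3,Septicemia/Shock,65-74,1824,2.08,0.65,0.28,24846,18825,67187,155969,NA
table3,COPD,65-74,2499,2.49,0.76,0.33,36931,22214,77822,179227,NA
table3,Heart diseases,75-84,1404,1.78,0.54,0.24,25881,16049,77648,174707,NA
table3,Septicemia/Shock,75-84,2856,1.60,0.49,0.22,22427,14590,75544,168258,NA
table3,COPD,75-84,4142,2.05,0.63,0.28,32472,18496,80902,182029,NA
table3,Respiratory diseases,75-84,1345,2.13,0.66,0.29,31907,19202,77438,176238,NA
table3,Heart diseases,>85,870,1.43,0.41,0.18,25015,12660,91891,209306,NA
table3,Septicemia/Shock,>85,1359,1.07,0.31,0.14,19194,11436,98808,218789,NA
table3,COPD,>85,2804,1.46,0.42,0.19,26736,12895,94361,208587,NA
results_text,Average patient,all,50481,NA,NA,NA,32352,27673,NA,NA,60025
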