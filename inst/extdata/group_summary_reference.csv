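variable,mean_ds,disp_ds,mean_nds,disp_nds,disp_kind
Age,50.26,8.37,49.88,7.80,sd
Education,8.30,2.80,9.05,2.57,sd
BMI,24.05,3.57,24.86,3.13,sd
Disease_course,27.93,7.69,26.54,8.03,sd
B1,3.64,0.12,1.71,0.10,se
B2,3.56,0.14,1.67,0.10,se
B3,3.66,0.16,1.50,0.11,se
B4,4.16,0.16,2.28,0.11,se
B5,3.50,0.13,1.56,0.13,se
B6,3.94,0.14,1.66,0.11,se
B7,3.54,0.14,1.52,0.11,se
B8,3.90,0.13,1.80,0.11,se
B9,3.02,0.15,1.21,0.10,se
B10,2.61,0.16,0.95,0.10,se
B11,2.96,0.16,1.07,0.10,se
B12,2.96,0.16,1.24,0.10,se
B13,3.47,0.18,1.56,0.12,se
BNSS_total,44.93,13.03,19.70,9.85,sd
Y1,12.97,4.08,5.36,3.39,sd
Y2,5.99,2.37,2.45,1.64,sd
Y3,3.94,1.19,1.66,1.06,sd
Y4,7.01,2.43,3.08,1.86,sd
SSPI,18.74,8.72,31.81,6.73,sd
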