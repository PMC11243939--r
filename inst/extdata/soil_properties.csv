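site_code,coarse_sand,fine_sand,silt,clay,texture_class,hygroscopic_humidity,density,pH_H2O,pH_KCl,CaCO3,humus,total_OC,OC_humic,OC_fulvic
R1,3.73,2.95,62.26,31.06,SCL,2.55,1.29,6.23,6.77,1.4,2.01,0.42,0.24,0.18
R2,4.12,3.27,63.42,29.19,SCL,2.62,1.33,6.38,6.75,1.28,2.37,0.38,0.22,0.16
R3,2.87,3.13,61.25,32.75,SCL,2.42,1.31,6.56,7,1.52,2.47,0.34,0.2,0.14
R4,9.23,7.11,56.31,27.35,SCL,2.84,1.3,7,7.56,1.2,2.08,0.4,0.27,0.13
R5,8.41,5.02,53.83,32.74,SCL,2.37,1.27,7.12,7.87,1.35,2.12,0.26,0.18,0.08
R6,7.97,6.28,52.48,33.27,SCL,2.22,1.25,7.35,7.92,1.64,2.63,0.23,0.14,0.09
NS1,12.99,16.59,33.47,36.95,CL,3.07,1.33,7.61,6.54,0.7,3.03,0.25,0.13,0.12
NS2,8.56,21.6,32.84,37,CL,3.15,1.3,7.43,6.58,NA,2.8,0.26,0.15,0.11
NS3,15.46,15.84,35.08,33.62,CL,3.2,1.31,7.8,6.93,2.52,2.86,0.24,0.18,0.06
NS4,12.68,24.53,34.85,27.95,SCL,2.65,1.35,7.76,7.15,4.21,2.29,0.18,0.05,0.13
NS5,12.01,20.45,33.42,34.12,CL,2.94,1.32,7.8,7.02,0.24,2.66,0.28,0.14,0.14
NS6,10.04,53.89,9.04,27.05,SaCL,3.17,1.39,7.58,6.73,NA,2.93,0.24,0.11,0.13
NS7,9.57,20.34,34.23,35.86,CL,3.1,1.36,7.68,6.86,1.26,2.97,0.33,0.11,0.22
NS8,8.32,22.22,34.93,34.56,CL,3.07,1.37,7.99,7.12,3.93,2.93,0.31,0.17,0.14
NS9,11.42,25.54,36.15,26.89,CL,2.71,1.34,7.67,7.12,6.88,2.52,0.26,0.19,0.07
NS10,11.49,6.88,44.09,37.54,SCL,3.15,1.38,7.69,6.98,1.26,2.36,0.25,0.12,0.13
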