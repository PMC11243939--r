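site_code,year,crop_type,organ,A,dA,censored
R1,2013,winter_wheat,root,1.72,0.26,FALSE
R2,2013,winter_wheat,root,1.5,0.23,FALSE
R3,2013,winter_wheat,root,1.37,0.21,FALSE
R4,2013,winter_wheat,root,1.6,0.24,FALSE
R5,2013,winter_wheat,root,1.05,0.16,FALSE
R6,2013,winter_wheat,root,1.13,0.17,FALSE
R1,2013,winter_wheat,rest_of_plant,0.51,0.07,FALSE
R2,2013,winter_wheat,rest_of_plant,0.46,0.07,FALSE
R3,2013,winter_wheat,rest_of_plant,0.45,0.07,FALSE
R4,2013,winter_wheat,rest_of_plant,0.53,0.08,FALSE
R5,2013,winter_wheat,rest_of_plant,0.46,0.07,FALSE
R6,2013,winter_wheat,rest_of_plant,0.49,0.07,FALSE
R1,2014,maize,root,1.38,0.22,FALSE
R2,2014,maize,root,1.32,0.21,FALSE
R3,2014,maize,root,0.93,0.14,FALSE
R4,2014,maize,root,1.67,0.25,FALSE
R5,2014,maize,root,1.38,0.22,FALSE
R6,2014,maize,root,1.48,0.22,FALSE
R1,2014,maize,stem,0.36,0.05,FALSE
R2,2014,maize,stem,0.29,0.04,FALSE
R3,2014,maize,stem,0.27,0.04,FALSE
R4,2014,maize,stem,0.44,0.06,FALSE
R5,2014,maize,stem,0.34,0.05,FALSE
R6,2014,maize,stem,0.38,0.06,FALSE
R1,2014,maize,leaf,0.68,0.11,FALSE
R2,2014,maize,leaf,0.64,0.09,FALSE
R3,2014,maize,leaf,0.58,0.08,FALSE
R4,2014,maize,leaf,0.8,0.12,FALSE
R5,2014,maize,leaf,0.54,0.07,FALSE
R6,2014,maize,leaf,0.6,0.09,FALSE
R1,2014,maize,grain,0.3,0.04,FALSE
R2,2014,maize,grain,0.27,0.04,FALSE
R3,2014,maize,grain,0.25,0.04,FALSE
R4,2014,maize,grain,0.35,0.05,FALSE
R5,2014,maize,grain,0.29,0.04,FALSE
R6,2014,maize,grain,0.31,0.04,FALSE
R1,2015,winter_wheat,root,1.37,0.21,FALSE
R2,2015,winter_wheat,root,1.24,0.19,FALSE
R3,2015,winter_wheat,root,1.14,0.17,FALSE
R4,2015,winter_wheat,root,1.47,0.22,FALSE
R5,2015,winter_wheat,root,0.77,0.11,FALSE
R6,2015,winter_wheat,root,0.79,0.15,FALSE
R1,2015,winter_wheat,rest_of_plant,0.33,0.05,FALSE
R2,2015,winter_wheat,rest_of_plant,0.31,0.05,FALSE
R3,2015,winter_wheat,rest_of_plant,0.28,0.04,FALSE
R4,2015,winter_wheat,rest_of_plant,0.36,0.06,FALSE
R5,2015,winter_wheat,rest_of_plant,0.26,0.04,FALSE
R6,2015,winter_wheat,rest_of_plant,0.28,0.05,FALSE
NS1,2013,winter_wheat,root,0.74,0.11,FALSE
NS4,2013,winter_wheat,root,0.96,0.14,FALSE
NS5,2013,winter_wheat,root,0.84,0.12,FALSE
NS9,2013,winter_wheat,root,0.93,0.14,FALSE
NS10,2013,rapeseed,root,0.52,0.08,FALSE
NS1,2013,winter_wheat,rest_of_plant,0.39,0.06,FALSE
NS4,2013,winter_wheat,rest_of_plant,0.45,0.06,FALSE
NS5,2013,winter_wheat,rest_of_plant,0.41,0.06,FALSE
NS9,2013,winter_wheat,rest_of_plant,0.43,0.07,FALSE
NS10,2013,rapeseed,rest_of_plant,0.23,0.03,FALSE
NS2,2013,maize,root,1.15,0.18,FALSE
NS3,2013,soybean,root,1.24,0.18,FALSE
NS6,2013,soybean,root,1.31,0.21,FALSE
NS7,2013,soybean,root,1.03,0.15,FALSE
NS8,2013,soybean,root,1.17,0.18,FALSE
NS2,2013,maize,stem,0.21,0.03,FALSE
NS3,2013,soybean,stem,0.82,0.12,FALSE
NS6,2013,soybean,stem,0.64,0.09,FALSE
NS7,2013,soybean,stem,0.57,0.09,FALSE
NS8,2013,soybean,stem,0.72,0.11,FALSE
NS2,2013,maize,leaf,0.95,0.14,FALSE
NS3,2013,soybean,leaf,0.98,0.14,FALSE
NS6,2013,soybean,leaf,1.17,0.18,FALSE
NS7,2013,soybean,leaf,0.89,0.13,FALSE
NS8,2013,soybean,leaf,0.93,0.14,FALSE
NS2,2013,maize,grain,0.14,NA,TRUE
NS3,2013,soybean,grain,0.27,0.04,FALSE
NS6,2013,soybean,grain,0.38,0.06,FALSE
NS7,2013,soybean,grain,0.31,0.05,FALSE
NS8,2013,soybean,grain,0.24,0.04,FALSE
NS1,2014,winter_wheat,root,0.74,0.11,FALSE
NS6,2014,winter_wheat,root,0.79,0.12,FALSE
NS7,2014,winter_wheat,root,0.86,0.13,FALSE
NS8,2014,winter_wheat,root,0.81,0.11,FALSE
NS10,2014,rapeseed,root,0.48,0.07,FALSE
NS1,2014,winter_wheat,rest_of_plant,0.35,0.05,FALSE
NS6,2014,winter_wheat,rest_of_plant,0.36,0.05,FALSE
NS7,2014,winter_wheat,rest_of_plant,0.42,0.06,FALSE
NS8,2014,winter_wheat,rest_of_plant,0.37,0.05,FALSE
NS10,2014,rapeseed,rest_of_plant,0.23,0.03,FALSE
NS2,2014,maize,root,1.17,0.18,FALSE
NS3,2014,soybean,root,1.2,0.18,FALSE
NS4,2014,maize,root,1.13,0.17,FALSE
NS5,2014,maize,root,1.07,0.16,FALSE
NS9,2014,soybean,root,1.27,0.19,FALSE
NS2,2014,maize,stem,0.19,0.03,FALSE
NS3,2014,soybean,stem,0.75,0.11,FALSE
NS4,2014,maize,stem,0.19,0.03,FALSE
NS5,2014,maize,stem,0.19,0.03,FALSE
NS9,2014,soybean,stem,0.66,0.09,FALSE
NS2,2014,maize,leaf,0.82,0.12,FALSE
NS3,2014,soybean,leaf,0.94,0.14,FALSE
NS4,2014,maize,leaf,0.81,0.12,FALSE
NS5,2014,maize,leaf,0.91,0.14,FALSE
NS9,2014,soybean,leaf,1.12,0.17,FALSE
NS2,2014,maize,grain,0.1,NA,TRUE
NS3,2014,soybean,grain,0.22,0.03,FALSE
NS4,2014,maize,grain,0.11,NA,TRUE
NS5,2014,maize,grain,0.08,NA,TRUE
NS9,2014,soybean,grain,0.2,0.03,FALSE
NS1,2015,winter_wheat,root,0.65,0.09,FALSE
NS4,2015,winter_wheat,root,0.88,0.13,FALSE
NS5,2015,winter_wheat,root,0.75,0.11,FALSE
NS9,2015,winter_wheat,root,0.81,0.11,FALSE
NS10,2015,rapeseed,root,0.47,0.07,FALSE
NS1,2015,winter_wheat,rest_of_plant,0.26,0.04,FALSE
NS4,2015,winter_wheat,rest_of_plant,0.32,0.05,FALSE
NS5,2015,winter_wheat,rest_of_plant,0.25,0.04,FALSE
NS9,2015,winter_wheat,rest_of_plant,0.21,0.03,FALSE
NS10,2015,rapeseed,rest_of_plant,0.19,0.03,FALSE
NS2,2015,maize,root,1.15,0.17,FALSE
NS3,2015,soybean,root,0.95,0.14,FALSE
NS6,2015,maize,root,1.08,0.16,FALSE
NS7,2015,maize,root,1.18,0.17,FALSE
NS8,2015,maize,root,1.03,0.15,FALSE
NS2,2015,maize,stem,0.13,0.02,FALSE
NS3,2015,soybean,stem,0.78,0.12,FALSE
NS6,2015,maize,stem,0.06,0.01,FALSE
NS7,2015,maize,stem,0.08,0.01,FALSE
NS8,2015,maize,stem,0.14,0.02,FALSE
NS2,2015,maize,leaf,1.07,0.16,FALSE
NS3,2015,soybean,leaf,0.84,0.13,FALSE
NS6,2015,maize,leaf,0.83,0.12,FALSE
NS7,2015,maize,leaf,0.82,0.12,FALSE
NS8,2015,maize,leaf,0.78,0.12,FALSE
NS2,2015,maize,grain,0.11,NA,TRUE
NS3,2015,soybean,grain,0.41,0.08,FALSE
NS6,2015,maize,grain,0.05,NA,TRUE
NS7,2015,maize,grain,0.06,NA,TRUE
NS8,2015,maize,grain,0.03,NA,TRUE
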