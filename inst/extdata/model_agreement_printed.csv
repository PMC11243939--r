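site_code,year,tf_mod,tf_exp,mean_ratio_printed
R1,2013,0.13,0.17,0.94
R1,2014,0.12,0.11,0.94
R1,2015,0.18,0.18,0.94
R2,2013,0.14,0.17,0.84
R2,2014,0.1,0.11,0.84
R2,2015,0.11,0.14,0.84
R3,2013,0.15,0.18,0.97
R3,2014,0.13,0.1,0.97
R3,2015,0.11,0.14,0.97
R4,2013,0.15,0.14,0.82
R4,2014,0.12,0.18,0.82
R4,2015,0.14,0.19,0.82
R5,2013,0.18,0.13,1.28
R5,2014,0.12,0.11,1.28
R5,2015,0.15,0.11,1.28
R6,2013,0.2,0.14,1.12
R6,2014,0.12,0.14,1.12
R6,2015,0.15,0.13,1.12
NS1,2013,0.25,0.17,1.29
NS1,2014,0.22,0.19,1.29
NS1,2015,0.19,0.15,1.29
NS2,2013,0.09,0.1,0.7
NS2,2014,0.08,0.12,0.7
NS2,2015,0.05,0.09,0.7
NS3,2013,0.31,0.32,1.06
NS3,2014,0.39,0.42,1.06
NS3,2015,0.39,0.3,1.06
NS4,2013,0.22,0.14,1.4
NS4,2014,0.08,0.07,1.4
NS4,2015,0.17,0.12,1.4
NS5,2013,0.23,0.15,1.17
NS5,2014,0.08,0.1,1.17
NS5,2015,0.16,0.15,1.17
NS6,2013,0.23,0.21,1.15
NS6,2014,0.22,0.15,1.15
NS6,2015,0.03,0.03,1.15
NS7,2013,0.26,0.23,0.88
NS7,2014,0.23,0.26,0.88
NS7,2015,0.03,0.05,0.88
NS8,2013,0.29,0.31,0.87
NS8,2014,0.22,0.2,0.87
NS8,2015,0.06,0.11,0.87
NS9,2013,0.22,0.16,1.16
NS9,2014,0.24,0.25,1.16
NS9,2015,0.12,0.11,1.16
NS10,2013,0.11,0.1,1.24
NS10,2014,0.22,0.16,1.24
NS10,2015,0.19,0.15,1.24
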