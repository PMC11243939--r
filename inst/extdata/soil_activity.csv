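site_code,year,A,dA
R1,2013,2.98,0.59
R2,2013,2.68,0.54
R3,2013,2.49,0.51
R4,2013,3.74,0.73
R5,2013,3.63,0.76
R6,2013,3.51,0.71
R1,2014,3.16,0.62
R2,2014,2.67,0.56
R3,2014,2.73,0.56
R4,2014,2.48,0.47
R5,2014,3.14,0.64
R6,2014,2.75,0.58
R1,2015,1.81,0.37
R2,2015,2.19,0.45
R3,2015,1.97,0.41
R4,2015,1.92,0.35
R5,2015,2.36,0.48
R6,2015,2.09,0.42
NS1,2013,2.25,0.45
NS2,2013,2.13,0.41
NS3,2013,2.56,0.53
NS4,2013,3.17,0.61
NS5,2013,2.83,0.54
NS6,2013,3.01,0.59
NS7,2013,2.45,0.49
NS8,2013,2.32,0.44
NS9,2013,2.69,0.54
NS10,2013,2.29,0.43
NS1,2014,1.88,0.38
NS2,2014,1.55,0.32
NS3,2014,1.78,0.39
NS4,2014,2.72,0.53
NS5,2014,1.99,0.39
NS6,2014,2.45,0.47
NS7,2014,1.64,0.33
NS8,2014,1.87,0.37
NS9,2014,2.25,0.43
NS10,2014,1.42,0.27
NS1,2015,1.72,0.33
NS2,2015,1.48,0.29
NS3,2015,1.64,0.32
NS4,2015,2.67,0.58
NS5,2015,1.67,0.32
NS6,2015,2.09,0.42
NS7,2015,1.54,0.41
NS8,2015,1.27,0.26
NS9,2015,1.98,0.41
NS10,2015,1.24,0.25
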