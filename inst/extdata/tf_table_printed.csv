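site_code,year,crop_type,organ,tf_printed
R1,2013,winter_wheat,root,0.58
R2,2013,winter_wheat,root,0.56
R3,2013,winter_wheat,root,0.55
R4,2013,winter_wheat,root,0.43
R5,2013,winter_wheat,root,0.29
R6,2013,winter_wheat,root,0.32
R1,2013,winter_wheat,rest_of_plant,0.17
R2,2013,winter_wheat,rest_of_plant,0.17
R3,2013,winter_wheat,rest_of_plant,0.18
R4,2013,winter_wheat,rest_of_plant,0.14
R5,2013,winter_wheat,rest_of_plant,0.13
R6,2013,winter_wheat,rest_of_plant,0.14
R1,2014,maize,root,0.44
R2,2014,maize,root,0.49
R3,2014,maize,root,0.34
R4,2014,maize,root,0.67
R5,2014,maize,root,0.44
R6,2014,maize,root,0.54
R1,2014,maize,stem,0.11
R2,2014,maize,stem,0.11
R3,2014,maize,stem,0.1
R4,2014,maize,stem,0.18
R5,2014,maize,stem,0.11
R6,2014,maize,stem,0.14
R1,2014,maize,leaf,0.22
R2,2014,maize,leaf,0.24
R3,2014,maize,leaf,0.21
R4,2014,maize,leaf,0.32
R5,2014,maize,leaf,0.17
R6,2014,maize,leaf,0.22
R1,2014,maize,grain,0.1
R2,2014,maize,grain,0.1
R3,2014,maize,grain,0.09
R4,2014,maize,grain,0.14
R5,2014,maize,grain,0.09
R6,2014,maize,grain,0.11
R1,2015,winter_wheat,root,0.76
R2,2015,winter_wheat,root,0.57
R3,2015,winter_wheat,root,0.58
R4,2015,winter_wheat,root,0.77
R5,2015,winter_wheat,root,0.33
R6,2015,winter_wheat,root,0.38
R1,2015,winter_wheat,rest_of_plant,0.18
R2,2015,winter_wheat,rest_of_plant,0.14
R3,2015,winter_wheat,rest_of_plant,0.14
R4,2015,winter_wheat,rest_of_plant,0.19
R5,2015,winter_wheat,rest_of_plant,0.11
R6,2015,winter_wheat,rest_of_plant,0.13
NS1,2013,winter_wheat,root,0.33
NS4,2013,winter_wheat,root,0.3
NS5,2013,winter_wheat,root,0.3
NS9,2013,winter_wheat,root,0.35
NS10,2013,rapeseed,root,0.23
NS1,2013,winter_wheat,rest_of_plant,0.17
NS4,2013,winter_wheat,rest_of_plant,0.14
NS5,2013,winter_wheat,rest_of_plant,0.14
NS9,2013,winter_wheat,rest_of_plant,0.16
NS10,2013,rapeseed,rest_of_plant,0.1
NS2,2013,maize,root,0.54
NS3,2013,soybean,root,0.48
NS6,2013,soybean,root,0.44
NS7,2013,soybean,root,0.42
NS8,2013,soybean,root,0.5
NS2,2013,maize,stem,0.1
NS3,2013,soybean,stem,0.32
NS6,2013,soybean,stem,0.21
NS7,2013,soybean,stem,0.23
NS8,2013,soybean,stem,0.31
NS2,2013,maize,leaf,0.45
NS3,2013,soybean,leaf,0.38
NS6,2013,soybean,leaf,0.39
NS7,2013,soybean,leaf,0.36
NS8,2013,soybean,leaf,0.4
NS2,2013,maize,grain,NA
NS3,2013,soybean,grain,0.11
NS6,2013,soybean,grain,0.13
NS7,2013,soybean,grain,0.13
NS8,2013,soybean,grain,0.1
NS1,2014,winter_wheat,root,0.39
NS6,2014,winter_wheat,root,0.32
NS7,2014,winter_wheat,root,0.52
NS8,2014,winter_wheat,root,0.43
NS10,2014,rapeseed,root,0.34
NS1,2014,winter_wheat,rest_of_plant,0.19
NS6,2014,winter_wheat,rest_of_plant,0.15
NS7,2014,winter_wheat,rest_of_plant,0.26
NS8,2014,winter_wheat,rest_of_plant,0.2
NS10,2014,rapeseed,rest_of_plant,0.16
NS2,2014,maize,root,0.76
NS3,2014,soybean,root,0.67
NS4,2014,maize,root,0.42
NS5,2014,maize,root,0.54
NS9,2014,soybean,root,0.56
NS2,2014,maize,stem,0.12
NS3,2014,soybean,stem,0.42
NS4,2014,maize,stem,0.07
NS5,2014,maize,stem,0.1
NS9,2014,soybean,stem,0.29
NS2,2014,maize,leaf,0.53
NS3,2014,soybean,leaf,0.53
NS4,2014,maize,leaf,0.3
NS5,2014,maize,leaf,0.46
NS9,2014,soybean,leaf,0.5
NS2,2014,maize,grain,NA
NS3,2014,soybean,grain,0.12
NS4,2014,maize,grain,NA
NS5,2014,maize,grain,NA
NS9,2014,soybean,grain,0.09
NS1,2015,winter_wheat,root,0.38
NS4,2015,winter_wheat,root,0.33
NS5,2015,winter_wheat,root,0.45
NS9,2015,winter_wheat,root,0.41
NS10,2015,rapeseed,root,0.38
NS1,2015,winter_wheat,rest_of_plant,0.15
NS4,2015,winter_wheat,rest_of_plant,0.12
NS5,2015,winter_wheat,rest_of_plant,0.15
NS9,2015,winter_wheat,rest_of_plant,0.11
NS10,2015,rapeseed,rest_of_plant,0.15
NS2,2015,maize,root,0.78
NS3,2015,soybean,root,0.58
NS6,2015,maize,root,0.52
NS7,2015,maize,root,0.77
NS8,2015,maize,root,0.81
NS2,2015,maize,stem,0.09
NS3,2015,soybean,stem,0.48
NS6,2015,maize,stem,0.03
NS7,2015,maize,stem,0.05
NS8,2015,maize,stem,0.11
NS2,2015,maize,leaf,0.72
NS3,2015,soybean,leaf,0.51
NS6,2015,maize,leaf,0.4
NS7,2015,maize,leaf,0.53
NS8,2015,maize,leaf,0.61
NS2,2015,maize,grain,NA
NS3,2015,soybean,grain,0.25
NS6,2015,maize,grain,NA
NS7,2015,maize,grain,NA
NS8,2015,maize,grain,NA
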