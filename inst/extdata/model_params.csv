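field,site_prefix,Kc,alpha_ex,CEC
Radmilovac,R,2.1,0.7,30
Rimski_Sancevi,NS,1.9,0.7,32
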