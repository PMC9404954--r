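trait,trait_type,side,h2,h2_se,p_value,n,covariate_prop,covariates,significant
LM1 2D area,area,L,0.611,0.110,<0.001,461,0.353,sex+age,TRUE
LM2 2D area,area,L,0.728,0.091,<0.001,537,0.413,sex+age,TRUE
LM3 2D area,area,L,0.261,0.190,0.260,221,0.490,sex,FALSE
RM1 2D area,area,R,0.703,0.132,<0.001,440,0.281,sex,TRUE
RM2 2D area,area,R,0.681,0.103,<0.001,531,0.366,sex,TRUE
RM3 2D area,area,R,0.726,0.275,0.004,171,0.508,sex,TRUE
L IC,gp,L,0.181,0.156,0.100,170,0.103,sex,FALSE
R IC,gp,R,0.604,0.333,0.006,127,0.094,sex,TRUE
L MMC,gp,L,0.001,0.141,0.496,191,0.082,sex+age,FALSE
L PMM,gp,L,0.491,0.093,<0.001,402,0.022,sex,TRUE
R MMC,gp,R,0.238,0.228,0.096,140,0.044,sex,FALSE
R PMM,gp,R,0.527,0.114,<0.001,380,0.030,sex,TRUE
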