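name,cell_line,log_papp_exp,efflux_ratio,stirring_rpm,source
syn0001,Caco-2,-4.45684,1,NA,synthetic
syn0002,Caco-2,-4.86221,1,150,synthetic
syn0003,Caco-2,-6.41958,1,600,synthetic
syn0004,Caco-2,-5.60946,1,600,synthetic
syn0005,MDCK,-6.06508,1,NA,synthetic
syn0006,MDCK,-5.47039,1,25,synthetic
syn0007,Caco-2,-3.96163,1,600,synthetic
syn0008,Caco-2,-4.15583,1,NA,synthetic
syn0009,Caco-2,-3.85249,1,600,synthetic
syn0010,MDCK,-4.29097,1,25,synthetic
syn0011,MDCK,-4.15288,1,25,synthetic
syn0012,MDCK,-6.72541,1,150,synthetic
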