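name,mw,log_khexw,d_hex,log_pm_exp
blm01,181.57,-0.30978,5.5184e-06,1.2428
blm02,158.53,-4.9539,1.1219e-05,-2.3622
blm03,294.07,-3.4248,4.4064e-06,-2.2593
blm04,65.936,-3.4052,1.1693e-05,-2.0212
blm05,255.53,-0.097095,7.7036e-06,1.2546
blm06,262.53,-1.6419,1.0535e-05,-0.19367
blm07,413.71,0.10804,3.3596e-06,1.0147
blm08,210.35,-1.6165,6.9275e-06,-0.43294
blm09,291.42,0.48972,1.2379e-05,2.6328
blm10,118.32,-2.799,3.0989e-06,-1.2093
blm11,327.5,-5.2858,4.2802e-06,-4.0491
blm12,445.8,0.70302,1.0129e-05,2.4501
blm13,168.96,1.8195,8.7965e-06,3.8927
blm14,223.3,-1.509,9.5304e-06,0.026299
blm15,390.77,-4.2228,6.6424e-06,-1.4735
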