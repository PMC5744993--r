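name,mw,log_khexw,log_klipw,d_aq_37,d_hex,d_lateral,stirring_rpm,chemical_class,f_neutral,f_cation,f_anion,f_dication,f_dianion,f_zwitterion
syn0001,280.825,2,3,6.09773e-06,7.29015e-06,1.13468e-08,NA,neutral,1,0,0,0,0,0
syn0002,243.254,-7,0,9.43256e-06,1.3872e-05,1.33413e-08,150,neutral,1,0,0,0,0,0
syn0003,464.242,1.15061,4.39211,5.12933e-06,9.9553e-06,2.08747e-08,600,permanent_ion,0,1,0,0,0,0
syn0004,92.2874,0.0282605,5.17368,1.2246e-05,1.85477e-05,1.95461e-08,600,permanent_ion,0,0,1,0,0,0
syn0005,401.412,-5.54465,2.84368,5.93843e-06,6.93444e-06,9.32205e-09,NA,zwitterion,0,0,0,0,0,1
syn0006,412.828,-3.7097,0.944066,6.21909e-06,6.44709e-06,2.63609e-08,25,permanent_ion,0,0,0,1,0,0
syn0007,659.302,-3.6863,2.41814,4.19021e-06,4.95952e-06,2.93067e-09,600,neutral,1,0,0,0,0,0
syn0008,327.74,0.283486,5.49954,6.00541e-06,7.01504e-06,1.53766e-08,NA,base,0.647965218258556,0.352034781741444,0,0,0,0
syn0009,459.919,-1.57027,1.44084,4.98648e-06,4.32647e-06,6.97132e-09,600,acid,0.971554461157415,0,0.0284455388425849,0,0,0
syn0010,177.697,0.529646,5.6791,8.55939e-06,1.31945e-05,2.4927e-08,25,acid,0.00590715327672664,0,0.994092846723273,0,0,0
syn0011,518.747,-1.53982,3.86692,4.48992e-06,5.02133e-06,7.77979e-09,25,diprotic,0.527927739421228,0.00110788845713369,0.225902302030648,0.136664439988997,0.101876381294807,0.00652124880718641
syn0012,711.624,0.987667,5.22617,4.57387e-06,4.5354e-06,2.48725e-08,150,permanent_ion,0,0.235956227953371,0.762634701175751,8.70375184336785e-06,0.00140036711903415,0
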