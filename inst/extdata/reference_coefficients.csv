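label,term,estimate,std_error
Eq3,(Intercept),-7.137,0.935
Eq3,log_km,0.272,0.079
Eq3,tpsa,-0.025,0.006
Eq3,alpha,0.041,0.030
Eq3,mw,0.003,0.003
Eq4,(Intercept),-6.109,0.540
Eq4,log_kw_iam,0.110,0.053
Eq4,tpsa,-0.044,0.002
Eq4,alpha,0.035,0.013
Eq4,mw,0.005,0.001
Eq5,(Intercept),-6.250,0.428
Eq5,log_kw_ods,0.157,0.058
Eq5,tpsa,-0.043,0.002
Eq5,alpha,0.034,0.012
Eq5,mw,0.004,0.001
Eq6,(Intercept),2.383,0.244
Eq6,log_km,0.063,0.022
Eq6,alpha,0.010,0.007
Eq6,mw,0.008,0.001
Eq7,(Intercept),2.412,0.4220
Eq7,log_kw_iam,0.018,0.043
Eq7,alpha,0.008,0.010
Eq7,mw,0.008,0.001
Eq8,(Intercept),2.356,0.3500
Eq8,log_kw_ods,0.019,0.049
Eq8,alpha,0.008,0.009
Eq8,mw,0.008,0.001
Eq9,(Intercept),-0.041,0.155
Eq9,log_km,0.017,0.020
Eq9,tpsa,-0.019,0.002
Eq9,alpha,0.043,0.007
Eq10,(Intercept),0.051,0.150
Eq10,log_kw_iam,0.033,0.017
Eq10,tpsa,-0.020,0.001
Eq10,alpha,0.041,0.006
Eq11,(Intercept),-0.005,0.133
Eq11,log_kw_ods,0.049,0.020
Eq11,tpsa,-0.020,0.001
Eq11,alpha,0.040,0.06
Eq12,(Intercept),159.92,28.86
Eq12,log_km,3.76,4.77
Eq12,tpsa,-1.90,0.29
Eq12,mw,0.47,0.13
Eq13,(Intercept),203.38,31.52
Eq13,log_kw_iam,10.08,4.16
Eq13,tpsa,-2.11,0.18
Eq13,mw,0.34,0.12
Eq14,(Intercept),183.81,26.42
Eq14,log_kw_ods,12.63,4.90
Eq14,tpsa,-2.04,0.17
Eq14,mw,0.35,0.11
Eq15,(Intercept),0.739,0.147
Eq15,log_km,-0.014,0.024
Eq15,tpsa,0.012,0.001
Eq15,mw,-0.003,0.001
Eq16,(Intercept),0.585,0.174
Eq16,log_kw_iam,-0.036,0.023
Eq16,tpsa,0.013,0.001
Eq16,mw,-0.003,0.001
Eq17,(Intercept),0.643,0.144
Eq17,log_kw_ods,-0.050,0.027
Eq17,tpsa,0.012,0.001
Eq17,mw,-0.003,0.001
Eq18,(Intercept),-6.780,0.470
Eq18,log_k01,0.079,0.122
Eq18,tpsa,-0.043,0.005
Eq18,alpha,0.042,0.017
Eq18,mw,0.006,0.001
Eq19,(Intercept),2.292,0.255
Eq19,log_k01,0.106,0.043
Eq19,alpha,0.010,0.007
Eq19,mw,0.008,0.001
Eq20,(Intercept),-0.052,0.155
Eq20,log_k01,0.033,0.043
Eq20,tpsa,-0.019,0.002
Eq20,alpha,0.042,0.007
Eq21,(Intercept),153.28,26.64
Eq21,log_k01,13.46,8.48
Eq21,tpsa,-1.75,0.28
Eq21,mw,0.43,0.11
Eq22,(Intercept),0.762,0.142
Eq22,log_k01,-0.038,0.045
Eq22,tpsa,0.012,0.001
Eq22,mw,-0.001,0.001
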