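label,response,predictors,n,r_squared,sd,f,p,max_vif,adj_r_squared,press,mse
Eq3,log_Kp,log_km;tpsa;alpha;mw,19,0.9593,0.108,83,0.000000,4.4,0.9476,0.279,0.012
Eq4,log_Kp,log_kw_iam;tpsa;alpha;mw,19,0.9677,0.096,106,0.000000,2.7,0.9585,0.220,0.009
Eq5,log_Kp,log_kw_ods;tpsa;alpha;mw,19,0.9723,0.089,123,0.000000,2.3,0.9644,0.170,0.008
Eq6,log_KaHSA,log_km;alpha;mw,19,0.9368,0.064,75,0.000000,1.3,0.9241,0.093,0.004
Eq7,log_KaHSA,log_kw_iam;alpha;mw,19,0.9031,0.079,47,0.000000,2.6,0.8837,0.153,0.006
Eq8,log_KaHSA,log_kw_ods;alpha;mw,19,0.9028,0.079,46,0.000000,2.1,0.8834,0.147,0.006
Eq9,log_BB,log_km;tpsa;alpha,19,0.9554,0.048,108,0.000000,2.6,0.9465,0.052,0.002
Eq10,log_BB,log_kw_iam;tpsa;alpha,19,0.9630,0.043,130,0.000000,1.8,0.9556,0.043,0.002
Eq11,log_BB,log_kw_ods;tpsa;alpha,19,0.9673,0.041,148,0.000000,1.8,0.9608,0.036,0.002
Eq12,caco2_e06,log_km;tpsa;mw,19,0.8799,9.723,37,0.000000,2.5,0.8559,2468,94.54
Eq13,caco2_e06,log_kw_iam;tpsa;mw,19,0.9101,8.413,51,0.000000,2.2,0.8921,1827,70.8
Eq14,caco2_e06,log_kw_ods;tpsa;mw,19,0.9133,8.260,53,0.000000,2,0.8960,1824,68.23
Eq15,fu_brain,log_km;tpsa;mw,19,0.9139,0.050,53,0.000000,2.5,0.8967,0.058,0.002
Eq16,fu_brain,log_kw_iam;tpsa;mw,19,0.9243,0.046,61,0.000000,2.2,0.9091,0.049,0.002
Eq17,fu_brain,log_kw_ods;tpsa;mw,19,0.9286,0.045,65,0.000000,2,0.9143,0.044,0.002
Eq18,log_Kp,log_k01;tpsa;alpha;mw,19,0.9590,0.109,82,0.000000,4.6,0.9473,0.284,0.012
Eq19,log_KaHSA,log_k01;alpha;mw,19,0.9300,0.067,67,0.000000,1.2,0.9160,0.111,0.005
Eq20,log_BB,log_k01;tpsa;alpha,19,0.9551,0.048,107,0.000000,3,0.9462,0.054,0.002
Eq21,caco2_e06,log_k01;tpsa;mw,19,0.8929,9.182,42,0.000000,2.3,0.8715,2311,84.32
Eq22,fu_brain,log_k01;tpsa;mw,19,0.9158,0.049,55,0.000000,2.3,0.8989,0.058,0.002
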