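compound_id,series,substituent,mw,tpsa,alpha,log_p,log_Kp,log_KaHSA,log_BB,caco2_e06,fu_brain
1,A,H,256.30,48.27,29.30,2.089,-6.061,4.80,0.230,187,0.52
2,A,4-CH3,270.33,48.27,31.06,2.701,-5.711,4.86,0.423,217,0.32
3,A,2-Cl,290.75,48.27,31.13,2.608,-5.800,5.09,0.339,215,0.33
4,A,3-Cl,290.75,48.27,31.13,2.757,-5.645,5.07,0.384,221,0.28
5,A,4-Cl,290.75,48.27,31.13,2.559,-5.817,5.16,0.328,208,0.38
6,A,"3,4-Cl2",325.19,48.27,32.95,3.250,-5.370,5.44,0.473,230,0.21
7,B,H,282.22,48.27,25.85,1.661,-6.021,4.96,0.102,196,0.44
8,B,2-CH3,296.25,48.27,27.61,2.273,-5.672,5.01,0.290,220,0.27
9,B,4-CH3,296.25,48.27,27.61,2.273,-5.672,5.01,0.290,220,0.27
10,B,2-OCH3,312.25,57.50,28.16,1.647,-6.245,5.03,0.063,195,0.43
11,B,2-Cl,316.67,48.27,27.68,2.151,-5.762,5.29,0.211,220,0.27
12,B,3-Cl,316.67,48.27,27.68,2.345,-5.603,5.31,0.264,221,0.26
13,B,4-Cl,316.67,48.27,27.68,2.131,-5.778,5.33,0.194,218,0.29
14,B,"3,4-Cl2",351.11,48.27,29.50,2.828,-5.332,5.64,0.345,235,0.14
15,C,H,286.29,74.57,30.27,0.931,-6.989,5.04,-0.243,134,0.73
16,C,4-CH3,300.31,74.57,32.02,1.548,-6.640,5.07,-0.051,169,0.59
17,C,3-Cl,320.73,74.57,32.09,1.605,-6.575,5.25,-0.090,179,0.55
18,C,4-Cl,320.73,74.57,32.09,1.401,-6.746,5.35,-0.151,170,0.59
19,C,"3,4-Cl2",355.18,74.57,33.91,2.132,-6.300,5.60,0.000,202,0.42
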