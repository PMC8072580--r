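compound_id,log_km,foley_r_squared,log_kw_iam,log_kw_ods
1,1.29,0.8851,0.76,1.59
2,1.68,0.9662,1.05,2.01
3,1.07,0.9725,0.65,1.42
4,2.28,0.9732,1.49,2.38
5,2.22,0.9754,1.39,2.32
6,2.82,0.9854,1.67,2.68
7,1.37,0.9862,0.94,1.92
8,0.92,0.9889,0.76,1.81
9,1.81,0.9870,1.25,2.16
10,0.88,0.9929,0.67,1.65
11,1.24,0.9947,0.88,1.86
12,2.52,0.9855,1.66,2.43
13,2.49,0.9911,1.58,2.40
14,2.70,0.9887,2.29,2.96
15,0.38,0.8467,0.48,1.21
16,0.74,0.9084,1.93,2.80
17,1.12,0.8604,1.73,2.62
18,1.12,0.8467,1.12,1.92
19,1.83,0.9117,3.36,3.24
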