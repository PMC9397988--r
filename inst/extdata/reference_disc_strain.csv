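bmi_class,traction_level,T12.L1,L1.L2,L2.L3,L3.L4,L4.L5,L5.S
normal,5,0.00147,0.00562,0.00749,0.00617,0.00418,0.00190
normal,7,0.00718,0.03595,0.05649,0.04362,0.03300,0.01448
normal,9,0.01642,0.05837,0.09232,0.07939,0.06654,0.04289
overweight,5,0.00106,0.00302,0.00306,0.00249,0.00186,0.000787
overweight,7,0.00531,0.02168,0.03104,0.02593,0.02031,0.01050
overweight,9,0.01204,0.05388,0.07949,0.06659,0.05503,0.02756
moderate_obese,5,0.00120,0.00190,0.00170,0.00127,0.00107,0.000647
moderate_obese,7,0.00514,0.0161,0.0213,0.0168,0.0142,0.00930
moderate_obese,9,0.00993,0.0329,0.0455,0.0371,0.0324,0.0233
extreme_obese,5,8.09e-06,6.30e-06,5.75e-06,5.04e-06,4.39e-06,4.51e-06
extreme_obese,7,0.00239,0.00709,0.00618,0.00464,0.00440,0.00403
extreme_obese,9,0.00399,0.0135,0.0189,0.0156,0.0141,0.0107
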