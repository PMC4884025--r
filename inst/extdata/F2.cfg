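x_max = 8.58
mu_max = 1.06
t_c = 4.12
phb_max = 0.71
mu_max_p = 0.89
t_c_p = 7.9
dpa_max = 0.18
mu_max_d = 0.72
t_c_d = 12.94
cry_max = 0.31
mu_max_c = 0.42
t_c_c = 12.77
y_dpa_x = 0.03
y_dpa_phb = 0.43
y_cry_phb = 2.53
glucose_g_per_l = 34.74
soybean_g_per_l = 14.73
label = F2
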