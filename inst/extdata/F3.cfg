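x_max = 10.09
mu_max = 0.9
t_c = 4.95
phb_max = 1.16
mu_max_p = 0.95
t_c_p = 8.39
dpa_max = 0.16
mu_max_d = 0.59
t_c_d = 15.77
cry_max = 0.53
mu_max_c = 0.4
t_c_c = 14.96
y_dpa_x = 0.018
y_dpa_phb = 0.21
y_cry_phb = 4.92
glucose_g_per_l = 44.42
soybean_g_per_l = 25.05
label = F3
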