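x_max = 5.58
mu_max = 0.78
t_c = 4.54
phb_max = 0.61
mu_max_p = 1.07
t_c_p = 8.46
dpa_max = 0.17
mu_max_d = 0.66
t_c_d = 14.12
cry_max = 0.19
mu_max_c = 0.2
t_c_c = 14.88
y_dpa_x = 0.025
y_dpa_phb = 1.02
y_cry_phb = 0.19
glucose_g_per_l = 25.1
soybean_g_per_l = 4.4
label = F1
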