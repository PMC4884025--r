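x_max = 13.07
mu_max = 0.86
t_c = 6.58
phb_max = 1.41
mu_max_p = 1.02
t_c_p = 8.88
dpa_max = 0.16
mu_max_d = 0.65
t_c_d = 14.32
cry_max = 0.78
mu_max_c = 0.33
t_c_c = 16.46
y_dpa_x = 0.0093
y_dpa_phb = 0.15
y_cry_phb = 5.83
glucose_g_per_l = 54.1
soybean_g_per_l = 35.37
label = F4
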