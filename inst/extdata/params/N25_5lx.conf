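# burst-and-coast model parameters (units: mm, s, rad; label in lx)
label = 5
gamma_R = 0.14
alpha = 0.78
gamma_w = 0.22
l_w = 22
l_w_noise = 22
tau0 = 0.71
tau_bar = 0.42
tau_min = 0.22
v_bar = 155
v_min = 0
l_bar = 58
gamma_att = 0.14
l_att = 90
d_att = 90
gamma_ali = 0.07
l_ali = 90
d_ali = 50
gamma_m = 1.2
l_m = 55
d_m = 10
l_c = 15
k = 2
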