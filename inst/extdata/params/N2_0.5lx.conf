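# burst-and-coast model parameters (units: mm, s, rad; label in lx)
label = 0.5
gamma_R = 0.26
alpha = 0.15
gamma_w = 0.15
l_w = 15
l_w_noise = 15
tau0 = 0.39
tau_bar = 0.26
tau_min = 0.22
v_bar = 155
v_min = 0
l_bar = 31
gamma_att = 0.4
l_att = 90
d_att = 30
gamma_ali = 0.45
l_ali = 80
d_ali = 50
gamma_m = 1.2
l_m = 40
d_m = 10
l_c = 15
k = 2
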