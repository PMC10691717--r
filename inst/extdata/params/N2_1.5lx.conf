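# burst-and-coast model parameters (units: mm, s, rad; label in lx)
label = 1.5
gamma_R = 0.4
alpha = 0.65
gamma_w = 0.2
l_w = 20
l_w_noise = 20
tau0 = 0.69
tau_bar = 0.38
tau_min = 0.22
v_bar = 155
v_min = 0
l_bar = 50
gamma_att = 0.6
l_att = 120
d_att = 30
gamma_ali = 0.37
l_ali = 115
d_ali = 50
gamma_m = 1.2
l_m = 50
d_m = 10
l_c = 15
k = 2
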