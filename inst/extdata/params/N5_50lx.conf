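# burst-and-coast model parameters (units: mm, s, rad; label in lx)
label = 50
gamma_R = 0.15
alpha = 0.8
gamma_w = 0.25
l_w = 25
l_w_noise = 25
tau0 = 0.79
tau_bar = 0.45
tau_min = 0.22
v_bar = 155
v_min = 0
l_bar = 62
gamma_att = 0.15
l_att = 250
d_att = 50
gamma_ali = 0.12
l_ali = 200
d_ali = 50
gamma_m = 1.2
l_m = 60
d_m = 10
l_c = 15
k = 2
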