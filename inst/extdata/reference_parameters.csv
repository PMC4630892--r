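grm,trait,breed,h2_p,h2_g,c_miss,r_g
G_W,navel,BB,0.34,0.38,0.48,0.12
G_W,navel,TC,0.29,0.50,0.37,0.12
G_W,coat_score,BB,0.36,0.39,0.48,0.07
G_W,coat_score,TC,0.32,0.44,0.42,0.07
G_W,coat_colour,BB,0.33,0.38,0.47,0.07
G_W,coat_colour,TC,0.34,0.39,0.46,0.07
G_W,body_condition,BB,0.21,0.57,0.27,0.63
G_W,body_condition,TC,0.18,0.58,0.24,0.63
G_W,yearling_weight,BB,0.39,0.42,0.48,0.04
G_W,yearling_weight,TC,0.36,0.39,0.48,0.04
G_S,navel,BB,0.08,0.88,0.08,0.93
G_S,navel,TC,0.09,0.86,0.10,0.93
G_S,coat_score,BB,0.16,0.77,0.18,0.83
G_S,coat_score,TC,0.14,0.79,0.15,0.83
G_S,coat_colour,BB,0.09,0.84,0.10,0.92
G_S,coat_colour,TC,0.06,0.91,0.06,0.92
G_S,body_condition,BB,0.10,0.85,0.10,0.92
G_S,body_condition,TC,0.08,0.88,0.08,0.92
G_S,yearling_weight,BB,0.06,0.92,0.06,0.96
G_S,yearling_weight,TC,0.08,0.88,0.08,0.96
G_D,navel,BB,0.10,0.85,0.11,-0.91
G_D,navel,TC,0.07,0.89,0.08,-0.91
G_D,coat_score,BB,0.12,0.83,0.13,-0.89
G_D,coat_score,TC,0.11,0.83,0.12,-0.89
G_D,coat_colour,BB,0.08,0.87,0.08,-0.93
G_D,coat_colour,TC,0.06,0.91,0.06,-0.93
G_D,body_condition,BB,0.08,0.88,0.08,-0.95
G_D,body_condition,TC,0.10,0.84,0.10,-0.95
G_D,yearling_weight,BB,0.07,0.90,0.07,-0.95
G_D,yearling_weight,TC,0.08,0.88,0.08,-0.95
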