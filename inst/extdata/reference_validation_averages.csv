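scheme,direction,grm,accuracy,bias
cross-breed within-sex,BB cows : TC cows,G_W,0.17,1.00
cross-breed within-sex,BB cows : TC cows,G_S,0.60,2.12
cross-breed within-sex,BB cows : TC cows,G_D,-0.51,-2.24
cross-breed within-sex,TC cows : BB cows,G_W,0.13,0.73
cross-breed within-sex,TC cows : BB cows,G_S,0.57,1.35
cross-breed within-sex,TC cows : BB cows,G_D,-0.56,-1.68
within-breed cross-sex,BB cows : BB bulls,G_W,0.21,0.90
within-breed cross-sex,BB cows : BB bulls,G_S,0.21,0.75
within-breed cross-sex,BB cows : BB bulls,G_D,0.18,0.72
within-breed cross-sex,TC cows : TC bulls,G_W,0.30,0.94
within-breed cross-sex,TC cows : TC bulls,G_S,0.31,0.83
within-breed cross-sex,TC cows : TC bulls,G_D,0.22,0.87
cross-breed cross-sex,BB cows : TC bulls,G_W,0.13,1.13
cross-breed cross-sex,BB cows : TC bulls,G_S,0.24,1.03
cross-breed cross-sex,BB cows : TC bulls,G_D,-0.09,-0.71
cross-breed cross-sex,TC cows : BB bulls,G_W,0.10,0.49
cross-breed cross-sex,TC cows : BB bulls,G_S,0.18,0.61
cross-breed cross-sex,TC cows : BB bulls,G_D,-0.08,-0.45
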