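scheme,direction,trait,grm,accuracy,bias
cross-breed within-sex,BB cows : TC cows,navel,G_W,0.40,1.65
cross-breed within-sex,BB cows : TC cows,navel,G_S,0.70,1.48
cross-breed within-sex,BB cows : TC cows,navel,G_D,-0.47,-2.00
cross-breed within-sex,BB cows : TC cows,coat_score,G_W,0.11,0.92
cross-breed within-sex,BB cows : TC cows,coat_score,G_S,0.64,3.77
cross-breed within-sex,BB cows : TC cows,coat_score,G_D,-0.54,-3.16
cross-breed within-sex,BB cows : TC cows,coat_colour,G_W,0.05,0.42
cross-breed within-sex,BB cows : TC cows,coat_colour,G_S,0.65,2.29
cross-breed within-sex,BB cows : TC cows,coat_colour,G_D,-0.62,-2.49
cross-breed within-sex,BB cows : TC cows,body_condition,G_W,0.20,1.42
cross-breed within-sex,BB cows : TC cows,body_condition,G_S,0.55,1.46
cross-breed within-sex,BB cows : TC cows,body_condition,G_D,-0.48,-1.85
cross-breed within-sex,BB cows : TC cows,yearling_weight,G_W,0.07,0.57
cross-breed within-sex,BB cows : TC cows,yearling_weight,G_S,0.45,1.61
cross-breed within-sex,BB cows : TC cows,yearling_weight,G_D,-0.43,-1.72
cross-breed within-sex,TC cows : BB cows,navel,G_W,0.14,0.61
cross-breed within-sex,TC cows : BB cows,navel,G_S,0.58,1.12
cross-breed within-sex,TC cows : BB cows,navel,G_D,-0.60,-2.03
cross-breed within-sex,TC cows : BB cows,coat_score,G_W,0.07,0.28
cross-breed within-sex,TC cows : BB cows,coat_score,G_S,0.53,0.76
cross-breed within-sex,TC cows : BB cows,coat_score,G_D,-0.57,-1.01
cross-breed within-sex,TC cows : BB cows,coat_colour,G_W,0.13,0.83
cross-breed within-sex,TC cows : BB cows,coat_colour,G_S,0.67,1.24
cross-breed within-sex,TC cows : BB cows,coat_colour,G_D,-0.66,-1.38
cross-breed within-sex,TC cows : BB cows,body_condition,G_W,0.20,1.22
cross-breed within-sex,TC cows : BB cows,body_condition,G_S,0.65,2.04
cross-breed within-sex,TC cows : BB cows,body_condition,G_D,-0.57,-2.27
cross-breed within-sex,TC cows : BB cows,yearling_weight,G_W,0.09,0.73
cross-breed within-sex,TC cows : BB cows,yearling_weight,G_S,0.43,1.56
cross-breed within-sex,TC cows : BB cows,yearling_weight,G_D,-0.38,-1.70
within-breed cross-sex,BB cows : BB bulls,navel,G_W,0.23,0.78
within-breed cross-sex,BB cows : BB bulls,navel,G_S,0.25,0.69
within-breed cross-sex,BB cows : BB bulls,navel,G_D,0.21,0.62
within-breed cross-sex,BB cows : BB bulls,coat_score,G_W,0.04,0.78
within-breed cross-sex,BB cows : BB bulls,coat_score,G_S,0.05,0.66
within-breed cross-sex,BB cows : BB bulls,coat_score,G_D,0.05,0.64
within-breed cross-sex,BB cows : BB bulls,coat_colour,G_W,0.40,1.65
within-breed cross-sex,BB cows : BB bulls,coat_colour,G_S,0.40,1.40
within-breed cross-sex,BB cows : BB bulls,coat_colour,G_D,0.37,1.42
within-breed cross-sex,BB cows : BB bulls,body_condition,G_W,0.15,0.39
within-breed cross-sex,BB cows : BB bulls,body_condition,G_S,0.17,0.32
within-breed cross-sex,BB cows : BB bulls,body_condition,G_D,0.11,0.30
within-breed cross-sex,BB cows : BB bulls,yearling_weight,G_W,0.20,0.90
within-breed cross-sex,BB cows : BB bulls,yearling_weight,G_S,0.20,0.67
within-breed cross-sex,BB cows : BB bulls,yearling_weight,G_D,0.17,0.60
within-breed cross-sex,TC cows : TC bulls,navel,G_W,0.56,1.26
within-breed cross-sex,TC cows : TC bulls,navel,G_S,0.56,1.07
within-breed cross-sex,TC cows : TC bulls,navel,G_D,0.33,1.45
within-breed cross-sex,TC cows : TC bulls,coat_score,G_W,0.29,0.65
within-breed cross-sex,TC cows : TC bulls,coat_score,G_S,0.29,0.56
within-breed cross-sex,TC cows : TC bulls,coat_score,G_D,0.28,0.61
within-breed cross-sex,TC cows : TC bulls,coat_colour,G_W,0.31,1.17
within-breed cross-sex,TC cows : TC bulls,coat_colour,G_S,0.30,0.98
within-breed cross-sex,TC cows : TC bulls,coat_colour,G_D,0.28,0.96
within-breed cross-sex,TC cows : TC bulls,body_condition,G_W,0.11,0.40
within-breed cross-sex,TC cows : TC bulls,body_condition,G_S,0.16,0.39
within-breed cross-sex,TC cows : TC bulls,body_condition,G_D,0.06,0.31
within-breed cross-sex,TC cows : TC bulls,yearling_weight,G_W,0.20,1.21
within-breed cross-sex,TC cows : TC bulls,yearling_weight,G_S,0.23,1.14
within-breed cross-sex,TC cows : TC bulls,yearling_weight,G_D,0.18,0.99
cross-breed cross-sex,BB cows : TC bulls,navel,G_W,0.32,1.95
cross-breed cross-sex,BB cows : TC bulls,navel,G_S,0.46,1.93
cross-breed cross-sex,BB cows : TC bulls,navel,G_D,-0.09,-0.71
cross-breed cross-sex,BB cows : TC bulls,coat_score,G_W,0.08,0.82
cross-breed cross-sex,BB cows : TC bulls,coat_score,G_S,0.23,0.93
cross-breed cross-sex,BB cows : TC bulls,coat_score,G_D,-0.20,-1.25
cross-breed cross-sex,BB cows : TC bulls,coat_colour,G_W,-0.06,-0.50
cross-breed cross-sex,BB cows : TC bulls,coat_colour,G_S,0.13,0.84
cross-breed cross-sex,BB cows : TC bulls,coat_colour,G_D,-0.17,-1.24
cross-breed cross-sex,BB cows : TC bulls,body_condition,G_W,0.22,1.04
cross-breed cross-sex,BB cows : TC bulls,body_condition,G_S,0.18,0.44
cross-breed cross-sex,BB cows : TC bulls,body_condition,G_D,0.07,-0.07
cross-breed cross-sex,BB cows : TC bulls,yearling_weight,G_W,0.09,1.32
cross-breed cross-sex,BB cows : TC bulls,yearling_weight,G_S,0.18,1.00
cross-breed cross-sex,BB cows : TC bulls,yearling_weight,G_D,-0.04,-0.25
cross-breed cross-sex,TC cows : BB bulls,navel,G_W,0.14,0.43
cross-breed cross-sex,TC cows : BB bulls,navel,G_S,0.20,0.45
cross-breed cross-sex,TC cows : BB bulls,navel,G_D,-0.12,-0.49
cross-breed cross-sex,TC cows : BB bulls,coat_score,G_W,0.09,0.41
cross-breed cross-sex,TC cows : BB bulls,coat_score,G_S,0.05,0.26
cross-breed cross-sex,TC cows : BB bulls,coat_score,G_D,0.03,0.10
cross-breed cross-sex,TC cows : BB bulls,coat_colour,G_W,0.05,0.46
cross-breed cross-sex,TC cows : BB bulls,coat_colour,G_S,0.27,1.04
cross-breed cross-sex,TC cows : BB bulls,coat_colour,G_D,-0.26,-1.15
cross-breed cross-sex,TC cows : BB bulls,body_condition,G_W,0.10,0.47
cross-breed cross-sex,TC cows : BB bulls,body_condition,G_S,0.15,0.39
cross-breed cross-sex,TC cows : BB bulls,body_condition,G_D,-0.02,-0.07
cross-breed cross-sex,TC cows : BB bulls,yearling_weight,G_W,0.10,0.70
cross-breed cross-sex,TC cows : BB bulls,yearling_weight,G_S,0.21,0.91
cross-breed cross-sex,TC cows : BB bulls,yearling_weight,G_D,-0.05,-0.29
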