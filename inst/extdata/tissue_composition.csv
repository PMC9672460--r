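tissue_name,f_extracellular_water,f_intracellular_water,f_neutral_lipid,f_neutral_phospholipid,albumin_ratio,intracellular_pH,surrogate
lung,0.336,0.446,0.022,0.0128,0.212,7.0,FALSE
heart,0.320,0.456,0.014,0.0111,0.157,7.0,FALSE
brain,0.162,0.620,0.039,0.0015,0.048,7.0,FALSE
adipose,0.135,0.017,0.845,0.0016,0.049,7.0,FALSE
muscle,0.118,0.630,0.010,0.0072,0.064,7.0,FALSE
skin,0.382,0.291,0.060,0.0044,0.277,7.0,FALSE
bone,0.100,0.346,0.017,0.0017,0.100,7.0,FALSE
gut,0.282,0.475,0.038,0.0125,0.158,7.0,FALSE
spleen,0.207,0.579,0.0077,0.0113,0.097,7.0,FALSE
liver,0.161,0.573,0.014,0.0240,0.086,7.0,FALSE
kidney,0.273,0.483,0.012,0.0242,0.130,7.0,FALSE
reproductive,0.255,0.525,0.017,0.0033,0.110,7.0,FALSE
rest_of_body,0.250,0.450,0.050,0.0080,0.100,7.0,TRUE
red_marrow,0.150,0.550,0.050,0.0050,0.100,7.0,TRUE
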