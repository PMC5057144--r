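tissue	water_mass_fraction	specific_gravity	lipid_fraction_of_dry	phospholipid_fraction_of_lipid	mass_attenuation_cm2_g
whole_brain	0.80	1.03	0.37	0.58	16.7
myelin	0.40	1.03	0.71	0.44	16.7
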