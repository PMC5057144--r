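material	energy_keV	value	kind
water	6.00	24.63	mass_cm2_g
water	8.00	10.37	mass_cm2_g
brain_gray_white	7.13	16.7	mass_cm2_g
phosphorus	7.13	109.0	mass_cm2_g
epoxy_resin	7.13	9.0	linear_cm_1
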