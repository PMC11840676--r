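species	charge	dGf0_kJ_mol	dHf0_kJ_mol	V0_cm3_mol	gamma	phase_rule
H2O	0	-237.18	-285.83	18.07	1.0	water
H+	1	0	0	0	1.0	proton
HCO3-	-1	-586.94	-692.0	24.6	0.532	aqueous
CH4	0	-34.35	-87.91	37.3	1.24	aqueous
H2	0	17.72	-4.2	25.2	1.24	aqueous
acetate	-1	-369.32	-486.0	40.5	0.532	aqueous
SO4-2	-2	-744.46	-909.6	13.9	0.104	aqueous
HS-	-1	12.05	-16.3	20.6	0.685	aqueous
methanol	0	-175.94	-246.0	38.2	1.0	aqueous
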