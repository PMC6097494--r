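model	phase	elec	elec_se	disp	disp_se	rep	rep_se
mTIP3P	water	-8.41	0.02	-2.72	0.00	4.80	0.05
TIP3P-FB	water	-9.78	0.02	-2.44	0.00	4.76	0.02
TIP4P-FB	water	-9.68	0.05	-2.77	0.00	4.95	0.02
mTIP3P	hexadecane	-0.22	0.04	-3.40	0.06	4.80	0.43
TIP3P-FB	hexadecane	-0.24	0.02	-3.33	0.09	4.69	0.52
TIP4P-FB	hexadecane	-0.23	0.03	-3.59	0.14	4.78	0.43
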