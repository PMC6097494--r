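model	P_m_1e-3_cm_s	se
mTIP3P	4.37	0.03
TIP3P-FB	0.76	0.02
TIP4P-FB	0.88	0.01
experiment	13.0	0.44
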