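chain_label	carbon_atom_name	hydrogen_atom_name
beta	C12	H12A
beta	C12	H12B
alpha	C11	H11A
alpha	C11	H11B
g3	C1	HA
g3	C1	HB
g2	C2	HS
g1	C3	HX
g1	C3	HY
sn1	C32	H2X
sn1	C32	H2Y
sn1	C33	H3X
sn1	C33	H3Y
sn1	C34	H4X
sn1	C34	H4Y
sn1	C35	H5X
sn1	C35	H5Y
sn1	C36	H6X
sn1	C36	H6Y
sn1	C37	H7X
sn1	C37	H7Y
sn1	C38	H8X
sn1	C38	H8Y
sn1	C39	H9X
sn1	C39	H9Y
sn1	C310	H10X
sn1	C310	H10Y
sn1	C311	H11X
sn1	C311	H11Y
sn1	C312	H12X
sn1	C312	H12Y
sn1	C313	H13X
sn1	C313	H13Y
sn1	C314	H14X
sn1	C314	H14Y
sn1	C315	H15X
sn1	C315	H15Y
sn1	C316	H16X
sn1	C316	H16Y
sn1	C316	H16Z
sn2	C22	H2R
sn2	C22	H2S
sn2	C23	H3R
sn2	C23	H3S
sn2	C24	H4R
sn2	C24	H4S
sn2	C25	H5R
sn2	C25	H5S
sn2	C26	H6R
sn2	C26	H6S
sn2	C27	H7R
sn2	C27	H7S
sn2	C28	H8R
sn2	C28	H8S
sn2	C29	H9R
sn2	C210	H10R
sn2	C211	H11R
sn2	C211	H11S
sn2	C212	H12R
sn2	C212	H12S
sn2	C213	H13R
sn2	C213	H13S
sn2	C214	H14R
sn2	C214	H14S
sn2	C215	H15R
sn2	C215	H15S
sn2	C216	H16R
sn2	C216	H16S
sn2	C217	H17R
sn2	C217	H17S
sn2	C218	H18R
sn2	C218	H18S
sn2	C218	H18T
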