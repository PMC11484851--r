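chain	resno	label	resid
A	318	h4s6.12	GLU
A	340	H5.12	THR
A	341	H5.13	ASP
A	342	H5.14	VAL
A	343	H5.15	ILE
A	344	H5.16	ILE
A	345	H5.17	LYS
A	346	H5.18	ASN
A	347	H5.19	ASN
A	348	H5.20	LEU
A	349	H5.21	LYS
A	350	H5.22	ASP
A	351	H5.23	CYS
A	352	H5.24	GLY
A	353	H5.25	LEU
A	354	H5.26	PHE
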