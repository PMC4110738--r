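id	name	neighbors
a1	CBK1	STE5,STE20,STE50
a2	PTC1	STE5,STE20
a3	CLA4	STE11,CDC24,CDC42,BEM1
a4	DSE1	STE11,STE4
a5	HOG1	STE11,STE7,STE50
a6	PBS2	STE11,BEM1
a7	SHO1	STE11,STE20,STE50,SST2,CDC24
a8	SPA2	STE11,STE7
a9	SPH1	STE11,STE7
a10	RGA2	STE20,CDC24,CDC42,BEM1
a11	CLN2	STE20,DIG1,DIG2,FAR1
a12	ENT2	CDC24,STE20
a13	EXO84	STE20,BEM1
a14	BOI1	STE20,FUS3,DIG1,DIG2,CDC24,CDC42,BEM1
a15	CDC28	STE20,FAR1,BEM1
a16	GIC1	STE50,CDC42
a17	GIC2	STE50,CDC24,CDC42
a18	BN1	FUS3,CDC42
a19	MPT5	FUS3,SST2
a20	KDX1	TEC1,DIG1,DIG2,STE12
a21	KSS1	STE5,STE11,STE7
a22	WHI3	TEC1,SST2,STE2
a23	BZZ1	DIG1,DIG2
a24	HMLALPHA1	DIG1,DIG2,STE12
a25	HYM1	DIG1,DIG2
a26	YCK2	DIG2,STE3
a27	RSR1	CDC42,BEM1,CDC24
a28	SEC15	CDC24,BEM1
a29	EXO70	CDC42,BEM1
a30	SEC3	CDC42,BEM1
a31	RHO1	BEM1,STE4
a32	SEC6	BEM1,STE2
a33	AKR1	BEM1,STE2
a34	DIB1	STE7,DIG1
a35	YHR131C	STE20,FUS3
a36	BDF2	STE20,FUS3
a37	SAS10	STE20,FUS3
a38	RBS1	DIG1,DIG2
a39	YJR003C	DIG1,DIG2
a40	AXL2	CDC24,CDC42,BEM1
a41	BEM4	STE20,CDC24,CDC42
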