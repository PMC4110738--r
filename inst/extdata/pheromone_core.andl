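# Curated core model of the S. cerevisiae pheromone response pathway.
# 46 places (species), 48 transitions (events).  The arc list is a curated
# reconstruction of the pathway's published qualitative structure; any file
# in this format satisfying the same structural checks can replace it.
# Tags: psi = core component protein given initial concentrations;
#       ste = Ste-family species (drives the pooling exemption);
#       fixed = technical-presence place whose tokens ship with the model.
# Arc flag R = regulatory (read) edge of weight one.
places
p1	alpha-factor	0	psi
p2	Ste2_receptor	0	psi,ste
p3	receptor_factor_complex	0	.
p4	receptor_complex	0	.
p5	trimer_bound_to_receptor	300	fixed
p6	G_alpha_GTP	0	.
p7	G_beta_gamma_dimer	0	.
p8	Cdc24	300	fixed
p9	Cdc42_at_pm	0	.
p10	Ste20	0	psi,ste
p11	Ste5_scaffold	0	psi,ste
p12	Ste5/Ste11	0	ste
p13	Fus3	0	psi
p14	Ste7/Fus3	0	.
p15	MAPK_complex	0	.
p16	Ste20_at_pm	0	ste
p17	complex2	0	.
p18	complex3	0	.
p19	complex4	0	.
p20	Fus3PP	0	.
p21	complex_without_Fus3	0	.
p22	repr_complex	300	fixed
p23	Dig1/Dig2	0	.
p24	free_Ste12	0	ste
p25	Ste12	0	ste
p26	Msg5	0	.
p27	Fus3_dephos	0	.
p28	other_genes	0	.
p29	Bar1_in_nucleus	0	.
p30	Bar1	0	.
p31	inactive_Far1	0	.
p32	Far1	0	.
p33	Far1_in_cytosol	0	.
p34	Sst2_in_nucleus	0	.
p35	phos_Sst2	0	.
p36	Sst2	0	.
p37	inactive_component	0	.
p38	phos_Kss1	0	.
p39	unphos_Kss1	0	.
p40	Akr1	0	psi
p41	Yck1/Yck2_at_pm	0	.
p42	inactive_receptor	0	.
p43	Ste11	0	psi,ste
p44	Ste50	0	psi,ste
p45	Bem1	0	psi
p46	Ste7	0	psi,ste
transitions
t1	MATalpha_cell(surroundings)	.
t2	binding_factor_to_receptor	.
t3	receptor_synthesis	.
t4	receptor_conformation_change	.
t5	division(in_alpha_subunit:GDP->GTP)	.
t6	hydrolysis_GTP->GDP	.
t7	interact_through_Far1	.
t8	Cdc42:GDP->GTP	.
t9	active_Cdc42_constitutive_at_pm	.
t10	Ste20_input	.
t11	Ste20_activated	.
t12	Ste5_input	.
t13	Ste5_binds_Ste11	exempt
t14	Fus3_synth	.
t15	Fus3_binds_Ste7	.
t16	complex-formation	.
t17	Ste20_phos_Ste11	.
t18	Ste11_phos_Ste7	.
t19	Ste7_phos_Fus3	.
t20	Fus3PP-release	.
t21	binding_free_Fus3	.
t22	Ste12_inhibit_phos	.
t23	Ste12-release	.
t24	Ste12_phos	.
t25	transcr_activation	.
t26	Fus3PP_dephos	.
t27	repression_through_Fus3	.
t28	cell_fusion	.
t29	transport_out_of_cell	.
t30	factor_destruction	.
t31	Far1_phos	.
t32	cell_cycle_arrest_in_G1	.
t33	transport_out_of_cell	.
t34	Sst2_phos	.
t35	transport_out_of_nucleus	.
t36	accelerated_hydr_GTP->GDP	.
t37	Ste11_neg_phos	.
t38	degradation	.
t39	Ste7_neg_phos	.
t40	Ste7_phos_Kss1	.
t41	accelerated-dephos-Kss1	.
t42	Kss1_dephos	.
t43	repression_through_Kss1	.
t44	tech_input	.
t45	Akr_synthesis	.
t46	Akr1_binds_Yck1/Yck2	.
t47	receptor_phos	.
t48	ubiquit_endocytosis	.
arcs
t1	p1	1	.
p1	t2	1	.
p2	t2	1	.
t2	p3	1	.
t3	p2	1	.
p3	t4	1	.
t4	p4	1	.
p4	t5	1	.
p5	t5	1	.
t5	p6	1	.
t5	p7	1	.
p6	t6	1	.
p7	t6	1	.
p7	t7	1	.
p33	t7	1	.
p8	t8	1	.
p45	t8	1	.
t8	p9	1	.
p8	t9	1	.
t9	p9	1	.
t10	p10	1	.
p9	t11	1	.
p45	t11	1	.
p10	t11	1	.
t11	p16	1	.
t12	p11	1	.
p11	t13	1	.
p43	t13	1	.
p44	t13	1	.
t13	p12	1	.
t14	p13	1	.
p13	t15	1	.
p46	t15	1	.
t15	p14	1	.
p12	t16	1	.
p14	t16	1	.
t16	p15	1	.
p15	t17	1	.
p16	t17	1	.
t17	p17	1	.
p17	t18	1	.
t18	p18	1	.
p18	t19	1	.
t19	p19	1	.
p19	t20	1	.
t20	p20	1	.
p21	t21	1	.
p13	t21	1	.
t21	p15	1	.
p22	t23	1	.
p23	t22	1	.
p20	t22	1	R
t23	p24	1	.
t23	p23	1	.
p20	t23	1	R
p24	t24	1	.
p20	t24	1	R
t24	p25	1	.
p25	t25	1	.
t25	p28	1	.
t25	p29	1	.
t25	p31	1	.
t25	p34	1	.
p26	t26	1	.
p20	t26	1	R
t26	p27	1	.
p27	t27	1	.
p23	t27	1	.
p24	t27	1	.
p28	t28	1	.
p29	t29	1	.
t29	p30	1	.
p30	t30	1	.
p1	t30	1	.
p31	t31	1	.
p20	t31	1	R
t31	p32	1	.
p32	t32	1	.
p32	t33	1	.
t33	p33	1	.
p34	t34	1	.
p20	t34	1	R
t34	p35	1	.
p35	t35	1	.
t35	p36	1	.
p6	t36	1	.
p7	t36	1	.
p36	t36	1	R
p15	t37	1	.
p20	t37	1	R
t37	p37	1	.
p37	t38	1	.
p21	t39	1	.
p20	t39	1	R
t39	p37	1	.
p39	t40	1	.
p46	t40	1	.
t40	p38	1	.
p38	t41	1	.
p20	t41	1	R
p38	t42	1	.
p26	t42	1	.
p39	t43	1	.
p23	t43	1	.
p24	t43	1	.
t44	p22	1	.
t45	p40	1	.
p40	t46	1	.
t46	p41	1	.
p4	t47	1	.
p41	t47	1	.
t47	p42	1	.
p42	t48	1	.
components
STE2	p2
STE3	p2
STE4	p7
STE5	p11
STE7	p46
STE11	p43
STE12	p25
STE18	p7
STE20	p10
STE50	p44
FUS3	p13
DIG1	p23
DIG2	p23
SST2	p36
FAR1	p33
CDC24	p8
CDC42	p9
BEM1	p45
GPA1	p6
TEC1	p25
AKR1	p40
BAR1	p30
MSG5	p26
KSS1	p38
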