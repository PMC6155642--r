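id	kind	structure	component	target	units	weight	provenance
co2_min_total	dimer_total	min	total	-1.23	kcal/mol	6	Table 1, Eint(MM), global minimum (CO2)2
co2_min_mumu	dimer_component_mumu	min	mumu	-1.00	kcal/mol	1	Table 1, Eint mu-mu (MM), minimum
co2_min_lj	dimer_component_lj	min	lj	-0.23	kcal/mol	1	Table 1, Eint LJ (MM), minimum
co2_parallel_total	dimer_total	parallel	total	0.16	kcal/mol	8	Sec 2.1 / Table 1, Eint(MM), parallel C-C 4.0 A
co2_parallel_mumu	dimer_component_mumu	parallel	mumu	0.32	kcal/mol	1	Table 1, Eint mu-mu (MM), parallel
co2_parallel_lj	dimer_component_lj	parallel	lj	-0.15	kcal/mol	1	Table 1, Eint LJ (MM), parallel
co2_T_total	dimer_total	T	total	-0.92	kcal/mol	6	Table 1, Eint(MM), T-type
co2_T_mumu	dimer_component_mumu	T	mumu	-0.70	kcal/mol	1	Table 1, Eint mu-mu (MM), T-type
co2_T_lj	dimer_component_lj	T	lj	-0.22	kcal/mol	1	Table 1, Eint LJ (MM), T-type
co2_freq_bend	frequency	co2	bend	629	cm-1	0	Table 1, nu(CO2) MM, degenerate bend
co2_freq_sym	frequency	co2	sym	1240	cm-1	0	Table 1, nu(CO2) MM, symmetric stretch
co2_freq_asym	frequency	co2	asym	2374	cm-1	0	Table 1, nu(CO2) MM, antisymmetric stretch
mea_nhn_total	dimer_total	NHN	total	-4.16	kcal/mol	6	Table 2, Eint Total (MM), NHN dimer
mea_nhn_mumu	dimer_component_mumu	NHN	mumu	-2.17	kcal/mol	1	Table 2, Eint mu-mu (MM), NHN dimer
mea_nhn_lj	dimer_component_lj	NHN	lj	-1.99	kcal/mol	1	Table 2, Eint vdW (MM), NHN dimer
mea_oho_total	dimer_total	OHO	total	-6.15	kcal/mol	6	Table 2, Eint Total (MM), OHO dimer
mea_oho_mumu	dimer_component_mumu	OHO	mumu	-4.33	kcal/mol	1	Table 2, Eint mu-mu (MM), OHO dimer
mea_oho_lj	dimer_component_lj	OHO	lj	-1.82	kcal/mol	1	Table 2, Eint vdW (MM), OHO dimer
co2_amino_motif	dimer_total	co2_amino	total	5.50	kcal/mol	4	Sec 2.5, |Eint| CO2 at the amino motif (MM)
co2_hydroxyl_motif	dimer_total	co2_hydroxyl	total	5.05	kcal/mol	4	Sec 2.5, |Eint| CO2 at the hydroxyl motif (MM)
scan_min_rcn	scan_minimum_distance	co2_amino	distance	2.7	angstrom	8	Sec 2.4, physisorption minimum of the C(CO2)-N(MEA) scan (MM)
co2_min_be_blypd2	context	min	total	-1.06	kcal/mol	0	Table 1, BE(BLYP-D2), minimum (context only)
co2_min_be_mp2	context	min	total	-1.27	kcal/mol	0	Table 1, BE(MP2), minimum (context only)
mea_nhn_be_blypd2	context	NHN	total	-4.62	kcal/mol	0	Table 2, BE(BLYP-D2), NHN (context only)
mea_oho_be_blypd2	context	OHO	total	-6.90	kcal/mol	0	Table 2, BE(BLYP-D2), OHO (context only)
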