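prediction_id	phenotype_id	measurement_id	reference_group	direction	lineage_origin	measurement_class
P01_XPB_AMH	parietal_breadth	XPB	AMH	1	NEA_DEN_ANCESTOR	LINEAR
P02_XPB_NEA	parietal_breadth	XPB	NEANDERTHAL	1	DEN_DERIVED	LINEAR
P03_MAL_AMH	maxilloalveolar_length	MAL	AMH	1	NEA_DEN_ANCESTOR	LINEAR
P04_MAL_NEA	maxilloalveolar_length	MAL	NEANDERTHAL	1	DEN_DERIVED	LINEAR
P05_GFA_AMH	glenoid_fossa_size	GFA	AMH	1	NEA_DEN_ANCESTOR	LINEAR
P06_GFA_NEA	glenoid_fossa_size	GFA	NEANDERTHAL	1	DEN_DERIVED	LINEAR
P07_ZYB_AMH	facial_breadth	ZYB	AMH	1	NEA_DEN_ANCESTOR	LINEAR
P08_ZYB_NEA	facial_breadth	ZYB	NEANDERTHAL	-1	NEA_DERIVED	LINEAR
P09_FPA_AMH	facial_protrusion	FPA	AMH	1	NEA_DEN_ANCESTOR	NONLINEAR
P10_FPA_NEA	facial_protrusion	FPA	NEANDERTHAL	-1	NEA_DERIVED	NONLINEAR
P11_MFI_AMH	malar_flattening	MFI	AMH	1	NEA_DEN_ANCESTOR	NONLINEAR
P12_MFI_NEA	malar_flattening	MFI	NEANDERTHAL	-1	NEA_DERIVED	NONLINEAR
P13_NPH_AMH	facial_height	NPH	AMH	1	AMH_DERIVED	LINEAR
P14_FRH_AMH	forehead_height	FRH	AMH	-1	AMH_DERIVED	LINEAR
P15_FRS_AMH	calvarial_curvature	FRS	AMH	-1	AMH_DERIVED	LINEAR
P16_GLS_AMH	glabellar_protrusion	GLS	AMH	1	AMH_DERIVED	LINEAR
P17_CBA_AMH	cranial_base_area	CBA	AMH	1	AMH_DERIVED	LINEAR
P18_OBH_AMH	orbital_height	OBH	AMH	1	AMH_DERIVED	LINEAR
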