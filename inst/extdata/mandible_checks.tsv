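specimen	prediction_id	phenotype	predicted_direction	observed_value	comparator_value	comparator_type	units	reported_relation	provenance
XIAHE_1	MAND_PROGNATHISM	superior_mandibular_length	1	NA	NA	median	mm	NA	measurement not available for Xiahe 1
PENGHU_1	MAND_PROGNATHISM	superior_mandibular_length	1	NA	NA	median	mm	GREATER	longer than Early H. sapiens median (published comparative figure)
XIAHE_1	ANT_MAND_WIDTH	bicanine_breadth	1	NA	NA	median	mm	GREATER	longer than Early H. sapiens median (published comparative figure)
PENGHU_1	ANT_MAND_WIDTH	bicanine_breadth	1	NA	NA	median	mm	GREATER	longer than Early H. sapiens median (published comparative figure)
XIAHE_1	ANT_MAND_HEIGHT	symphyseal_height	1	NA	NA	median	mm	GREATER	longer than Early H. sapiens (published comparative figure)
PENGHU_1	ANT_MAND_HEIGHT	symphyseal_height	1	NA	NA	median	mm	LESS	shorter than Early H. sapiens median (published comparative figure)
XIAHE_1	CONDYLAR_SIZE	condylar_head_area	1	NA	133.63	mean	mm2	NA	condyle of Xiahe 1 is missing
PENGHU_1	CONDYLAR_SIZE	condylar_head_area	1	189.34	133.63	mean	mm2	NA	ellipse-approximated condylar area vs modern male sample mean
XIAHE_1	DENTAL_ARCH_AMH	dental_arcade_length	1	55.7	52.58	weighted_mean	mm	NA	arcade length vs pooled H. sapiens weighted mean
XIAHE_1	DENTAL_ARCH_NEA	dental_arcade_length	1	55.7	54.78	weighted_mean	mm	NA	arcade length vs pooled Neanderthal weighted mean
PENGHU_1	DENTAL_ARCH_AMH	dental_arcade_length	1	NA	NA	median	mm	GREATER	inferred longer arcade via arcade index and arch widths
PENGHU_1	DENTAL_ARCH_NEA	dental_arcade_length	1	NA	NA	median	mm	GREATER	inferred longer arcade via arcade index and arch widths
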