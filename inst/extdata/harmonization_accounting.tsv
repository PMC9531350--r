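phenotype	source_id	n_snps	n_missing	missing_pct	contains_xy
Inflammatory bowel disease	PGS000017	6907112	0	NA	FALSE
Lupus	PGS000328	57	NA	6.14	FALSE
Breast cancer	PGS000015	5218	0	NA	FALSE
Prostate cancer	PGS000333	6606785	832	0.01	FALSE
Glaucoma	PGS000137	2673	16	0.60	FALSE
Testicular cancer	PRSWEB_187.2	43	0	NA	FALSE
Chronic lymph leukaemia	PRSWEB_204.12	27	0	NA	FALSE
Thyroid cancer	PRSWEB_193	5	0	NA	FALSE
Glioma	PRSWEB_191.1	19	0	NA	FALSE
Melanoma	PRSWEB_172.1	27	1	3.70	FALSE
Colorectal cancer	PRSWEB_153	87	1	1.15	FALSE
Basal cell carcinoma	PRSWEB_172.21	24	1	4.17	FALSE
Atrial fibrillation	PGS000016	6730541	0	NA	FALSE
Coronary Artery Disease	PGS000013	6630150	0	NA	FALSE
Ischaemic stroke	PGS000039	3225583	11103	0.34	FALSE
Type 2 diabetes	PGS000014	6917436	0	NA	FALSE
Testosterone levels (female)	PGS000323	7168	NA	NA	TRUE
Testosterone levels (male)	PGS000322	8235	NA	NA	TRUE
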