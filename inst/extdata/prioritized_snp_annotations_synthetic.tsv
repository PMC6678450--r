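entry_id	dbsnp_id	gene	hgvs_c	hgvs_p	hgvs_g	chromosome	position	phenotype	pubmed_id	study_type	p_value	odds_ratio	ci_low	ci_high	n_participants	population_studied	effect_allele	effect_class
T2E01	rs9997745	ACSL1				4	1000000	Metabolic Syndrome	30000001	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E02	rs6008259	PPARA				22	2000000	Hypercholesterolemia	30000002	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E03	rs6087990	DNMT3B				20	3000000	Colorectal Cancer	30000003	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E04	rs3790433	LEPR				1	4000000	Metabolic Syndrome	30000004	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E05	rs11568820	VDR				12	5000000	Prostate Cancer	30000005	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E06	rs512535	APOB				2	6000000	Metabolic Syndrome	30000006	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E07	rs10495563	ADAM17				2	7000000	Obesity	30000007	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E08	rs2287161	CRY1				12	8000000	Metabolic Syndrome	30000008	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E09	rs3827730	FAF1				1	9000000	Alcohol Dependence	30000009	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E10	rs2424913	DNMT3B				20	10000000	Adenoma, Colorectal Cancer	30000010	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E11	rs1801181	CBS				21	11000000	Colorectal Cancer	30000011	candidate	0.01	0.6	0.4	0.9	500	synthetic placeholder	A	protective
T2E12	rs2424909	DNMT3B				20	12000000	Colorectal Cancer	30000012	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E13	rs1378942	CSK				15	13000000	Hypertension	30000013	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E14	rs2168784	(Intergenic)				3	14000000	Alcohol dependence	30000014	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
T2E15	rs1229984	ADH1B				4	15000000	Alcohol dependence	30000015	candidate	0.01	0.6	0.4	0.9	500	synthetic placeholder	A	protective
T2E16	rs75038630	NADSYN1				11	16000000	Abnormal Eating Behavior	30000016	candidate	0.01	1.5	1.1	2	500	synthetic placeholder	A	risk
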