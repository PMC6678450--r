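dbsnp_id	gene	phenotype	dietary_change	ALL	AFR	AMR	EAS	EUR	SAS
rs9997745	ACSL1	Metabolic Syndrome	Low-fat (<35% energy), high-PUFA diet (>5.5% energy)	78	40	87	100	85	93
rs6008259	PPARA	Hypercholesterolemia	Low n–6 fatty Acid (≤7.99 g/day)	73	86	24	100	82	92
rs6087990	DNMT3B	Colorectal Cancer	High RBC folate	68	76	63	92	37	68
rs3790433	LEPR	Metabolic Syndrome	Low n-6 PUFA, high n-3 PUFA	59	23	67	84	77	58
rs11568820	VDR	Prostate Cancer	Low calcium (<680 mg/day)	54	11	82	60	77	64
rs512535	APOB	Metabolic Syndrome	Low fat (<35% energy)	53	19	51	81	51	73
rs10495563	ADAM17	Obesity	Low n-6 fatty Acid	52	30	56	90	34	58
rs2287161	CRY1	Metabolic Syndrome	Low carbohydrate (% of energy intake <41.7%)	46	64	52	13	45	54
rs3827730	FAF1	Alcohol Dependence	Low amounts of alcohol	38	7	52	79	35	28
rs2424913	DNMT3B	Adenoma, Colorectal Cancer	No alcohol	31	33	36	1	59	29
rs1801181	CBS	Colorectal Cancer	High RBC folate	30	2	19	57	39	36
rs2424909	DNMT3B	Colorectal Cancer	Moderate alcohol >0 and <1.7 drinks/week	28	8	36	8	63	31
rs1378942	CSK	Hypertension	1.8 g/day of EPA and DHA	24	3	33	18	61	16
rs2168784	(Intergenic)	Alcohol dependence	no alcoholic drinks/week	24	62	10	9	10	13
rs1229984	ADH1B	Alcohol dependence	no alcoholic drinks/week	16	0	6	70	3	2
rs75038630	NADSYN1	Abnormal Eating Behavior	High vitamin D (>75 nmol/L)	2	0	4	100	6	3
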