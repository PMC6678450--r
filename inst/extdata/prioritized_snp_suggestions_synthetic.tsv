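suggestion_id	entry_id	suggestion_type	item	direction	quantity	units	interaction_p	interaction_or	interaction_ci_low	interaction_ci_high	description
T2S01	T2E01	nutrient	fat	decrease	35	% energy					Low-fat (<35% energy), high-PUFA diet (>5.5% energy)
T2S02	T2E02	nutrient	n-6 fatty acid	decrease	7.99	g/day					Low n–6 fatty Acid (≤7.99 g/day)
T2S03	T2E03	nutrient	folate	increase							High RBC folate
T2S04	T2E04	nutrient	n-3 PUFA	increase							Low n-6 PUFA, high n-3 PUFA
T2S05	T2E05	nutrient	calcium	decrease	680	mg/day					Low calcium (<680 mg/day)
T2S06	T2E06	nutrient	fat	decrease	35	% energy					Low fat (<35% energy)
T2S07	T2E07	nutrient	n-6 fatty acid	decrease							Low n-6 fatty Acid
T2S08	T2E08	nutrient	carbohydrate	decrease	41.7	% energy					Low carbohydrate (% of energy intake <41.7%)
T2S09	T2E09	food	alcohol	decrease							Low amounts of alcohol
T2S10	T2E10	food	alcohol	avoid	0	drinks/week					No alcohol
T2S11	T2E11	nutrient	folate	increase							High RBC folate
T2S12	T2E12	food	alcohol	moderate	1.7	drinks/week					Moderate alcohol >0 and <1.7 drinks/week
T2S13	T2E13	nutrient	EPA and DHA	increase	1.8	g/day					1.8 g/day of EPA and DHA
T2S14	T2E14	food	alcohol	avoid	0	drinks/week					no alcoholic drinks/week
T2S15	T2E15	food	alcohol	avoid	0	drinks/week					no alcoholic drinks/week
T2S16	T2E16	nutrient	vitamin D	increase	75	nmol/L					High vitamin D (>75 nmol/L)
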