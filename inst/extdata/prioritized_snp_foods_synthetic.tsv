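suggestion_id	food_name	nutrient_content_per_serving	servings_for_daily_value
T2S01	synthetic low-fat staple	5	2
T2S02	synthetic low n-6 oil	4	2
T2S03	synthetic leafy green	120	3.3
T2S04	synthetic oily fish	1.2	1.5
T2S05	synthetic low-calcium grain	60	11.3
T2S06	synthetic low-fat staple	5	2
T2S07	synthetic low n-6 oil	4	2
T2S08	synthetic low-carbohydrate vegetable	8	5
T2S09	synthetic non-alcoholic beverage	0	1
T2S10	synthetic non-alcoholic beverage	0	1
T2S11	synthetic leafy green	120	3.3
T2S12	synthetic non-alcoholic beverage	0	1
T2S13	synthetic oily fish	1.6	1.1
T2S14	synthetic non-alcoholic beverage	0	1
T2S15	synthetic non-alcoholic beverage	0	1
T2S16	synthetic fortified milk	2.5	4
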