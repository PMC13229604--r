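icd_version	icd_code	phecode_id	phecode_label	disease_group
9	311	296.20	Depression	mental disorders
10	F32.9	296.20	Depression	mental disorders
9	296.2	296.22	Major depressive disorder	mental disorders
10	F33.1	296.22	Major depressive disorder	mental disorders
9	300.00	300.00	Anxiety disorder	mental disorders
10	F41.9	300.00	Anxiety disorder	mental disorders
9	296.90	296.00	Mood disorders	mental disorders
10	F39	296.00	Mood disorders	mental disorders
9	309.9	304.00	Adjustment reaction	mental disorders
10	F43.20	304.00	Adjustment reaction	mental disorders
9	304.90	316.00	Substance addiction and disorders	mental disorders
10	F19.99	316.00	Substance addiction and disorders	mental disorders
9	305.1	318.00	Tobacco use disorder	mental disorders
10	F17.200	318.00	Tobacco use disorder	mental disorders
9	303.90	317.00	Alcoholism	mental disorders
10	F10.20	317.00	Alcoholism	mental disorders
9	780.57	327.30	Sleep apnea	sleep disorders
10	G47.30	327.30	Sleep apnea	sleep disorders
9	780.52	327.40	Insomnia	sleep disorders
10	G47.00	327.40	Insomnia	sleep disorders
9	278.00	278.10	Obesity	endocrine/metabolic
10	E66.9	278.10	Obesity	endocrine/metabolic
9	278.01	278.11	Morbid obesity	endocrine/metabolic
10	E66.01	278.11	Morbid obesity	endocrine/metabolic
9	250.00	250.20	Type 2 diabetes	endocrine/metabolic
10	E11.9	250.20	Type 2 diabetes	endocrine/metabolic
9	272.4	272.10	Hyperlipidemia	endocrine/metabolic
10	E78.5	272.10	Hyperlipidemia	endocrine/metabolic
9	244.9	244.00	Hypothyroidism	endocrine/metabolic
10	E03.9	244.00	Hypothyroidism	endocrine/metabolic
9	401.9	401.10	Essential hypertension	circulatory system
10	I10	401.10	Essential hypertension	circulatory system
9	414.01	411.40	Coronary atherosclerosis	circulatory system
10	I25.10	411.40	Coronary atherosclerosis	circulatory system
9	427.31	427.20	Atrial fibrillation	circulatory system
10	I48.91	427.20	Atrial fibrillation	circulatory system
9	428.0	428.20	Heart failure	circulatory system
10	I50.9	428.20	Heart failure	circulatory system
9	493.90	495.00	Asthma	respiratory
10	J45.909	495.00	Asthma	respiratory
9	496	496.00	Chronic obstructive pulmonary disease	respiratory
10	J44.9	496.00	Chronic obstructive pulmonary disease	respiratory
9	530.81	530.11	Gastroesophageal reflux disease	digestive
10	K21.9	530.11	Gastroesophageal reflux disease	digestive
9	564.1	564.10	Irritable bowel syndrome	digestive
10	K58.9	564.10	Irritable bowel syndrome	digestive
9	585.9	585.30	Chronic kidney disease	genitourinary
10	N18.9	585.30	Chronic kidney disease	genitourinary
9	346.90	340.00	Migraine	neurological
10	G43.909	340.00	Migraine	neurological
9	780.93	350.20	Memory loss	neurological
10	R41.3	350.20	Memory loss	neurological
9	715.90	740.10	Osteoarthritis	musculoskeletal
10	M19.90	740.10	Osteoarthritis	musculoskeletal
9	724.5	760.00	Back pain	musculoskeletal
10	M54.9	760.00	Back pain	musculoskeletal
9	692.9	686.10	Dermatitis	dermatologic
10	L30.9	686.10	Dermatitis	dermatologic
9	173.9	172.20	Skin cancer	neoplasms
10	C44.90	172.20	Skin cancer	neoplasms
9	079.99	079.00	Viral infection	infectious diseases
10	B34.9	079.00	Viral infection	infectious diseases
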