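code_type	code	category
icd9	780.52	insomnia
icd10	G47.00	insomnia
icd10	F51.01	insomnia
icd9	780.57	breathing
icd9	327.23	breathing
icd10	G47.30	breathing
icd10	G47.33	breathing
icd9	780.50	other_sleep
icd10	G47.8	other_sleep
icd10	G47.9	other_sleep
icd10	G25.81	other_sleep
medication	ZOLPIDEM	medication
medication	ESZOPICLONE	medication
medication	TRAZODONE	medication
medication	TEMAZEPAM	medication
medication	MELATONIN	medication
medication	RAMELTEON	medication
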