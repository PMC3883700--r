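process	direction	es	sum_of_genes	early	medium	late
regulation of transcription	up	3.38	99	40	54	48
histone acetylation	up	2.28	19	7	9	10
RNA processing and transport	up	2.20	30	11	16	11
protein transport	down	4.04	69	32	19	24
glycolysis	down	3.05	13	9	3	3
cellular respiration	down	2.20	37	14	12	13
endocytosis	down	2.12	26	16	7	9
regulation of protein ubiquitination	down	2.02	38	19	16	10
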