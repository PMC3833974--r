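outcome	material	n_factors_significant	cv_coverage	cv_accuracy	n_rules	n_validatable_rules	n_validated_rules
Allergic asthma	birth_cohort	13	92.3	57.0	61	4	3
Allergic asthma	cross_sectional	8	79.6	53.4	18	0	0
Non-allergic asthma	birth_cohort	16	92.7	58.2	70	2	2
Non-allergic asthma	cross_sectional	10	84.9	56.3	37	1	1
Asthma	birth_cohort	9	47.2	56.6	21	2	2
Asthma	cross_sectional	17	95.3	52.0	111	1	1
Current asthma	birth_cohort	12	76.4	56.0	34	3	3
Current asthma	cross_sectional	9	94.4	56.5	53	4	3
Atopic sensitization >3.5 kU/L	birth_cohort	4	4.2	67.7	3	1	1
Atopic sensitization >3.5 kU/L	cross_sectional	6	18.7	47.5	3	1	1
Atopic sensitization >0.35 kU/L	birth_cohort	18	93.6	50.2	124	1	0
Atopic sensitization >0.35 kU/L	cross_sectional	21	93.9	49.2	184	0	0
Allergic eczema	birth_cohort	5	33.2	57.1	11	1	1
Allergic eczema	cross_sectional	8	46.2	56.9	29	1	1
Eczema	birth_cohort	8	49.8	54.5	17	0	0
Eczema	cross_sectional	11	73.2	56.2	45	3	2
Non-allergic eczema	birth_cohort	10	92.0	56.1	41	2	0
Non-allergic eczema	cross_sectional	7	23.5	58.8	7	2	2
Rhinoconjunctivitis	birth_cohort	9	42.4	47.5	18	0	0
Rhinoconjunctivitis	cross_sectional	5	16.4	61.5	7	1	1
Wheeze	birth_cohort	18	90.5	57.4	121	6	5
Wheeze	cross_sectional	21	93.8	52.9	106	3	2
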