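label	characteristic	n_respondents	weighted_pct	self_reported_est	self_reported_ci_low	self_reported_ci_high	corrected_est	corrected_ci_low	corrected_ci_high
Overall	overall	344087	100	5.3	5.1	5.4	8.8	8.6	9.0
Men	sex	164001	50.5	4.2	4.0	4.5	6.5	6.2	6.8
Women	sex	180086	49.5	6.3	6.1	6.6	11.1	10.8	11.5
18-34	age_group	59991	29.6	4.6	4.3	4.9	9.5	9.0	10.1
35-49	age_group	66676	22.9	6.9	6.5	7.3	10.3	9.8	10.9
50-64	age_group	94700	25.1	6.2	5.7	6.6	10.0	9.5	10.5
65+	age_group	122720	22.4	3.5	3.2	3.7	4.9	4.6	5.2
Hispanic	race_ethnicity	26159	16.3	5.4	4.8	6.1	10.4	9.5	11.4
Non-Hispanic Asian	race_ethnicity	8130	5.5	1.3	0.9	2.1	2.3	1.7	3.3
Non-Hispanic Black	race_ethnicity	26435	12.0	9.6	8.7	10.4	14.6	13.7	15.5
Non-Hispanic White	race_ethnicity	266146	63.1	4.7	4.5	4.9	7.8	7.6	8.0
Other Non-Hispanic	race_ethnicity	17217	3.1	6.1	5.4	6.9	9.6	8.8	10.5
Less than high school graduate	education	21190	11.7	7.7	6.9	8.6	12.4	11.4	13.5
High school graduate or equivalent	education	91992	27.8	5.7	5.4	6.1	9.5	9.1	10.0
Some college	education	96233	31.2	5.7	5.4	6.1	9.6	9.2	10.1
College graduate	education	134105	29.3	3.4	3.2	3.5	5.8	5.5	6.0
Married or domestic partnership	marital_status	190904	55.2	4.7	4.5	4.9	7.9	7.6	8.2
Not married	marital_status	151906	44.8	6.0	5.7	6.3	9.8	9.5	10.2
Employed	employment	173685	55.9	5.1	4.8	5.3	8.6	8.3	8.9
Unemployed	employment	64907	24.3	6.9	6.5	7.4	11.9	11.3	12.5
Retired	employment	103483	19.8	3.8	3.5	4.2	5.6	5.2	6.0
Northeast	census_region	64515	16.6	4.3	4.0	4.6	7.1	6.7	7.5
Midwest	census_region	97988	21.0	5.9	5.6	6.1	10.0	9.6	10.4
South	census_region	100122	38.4	5.9	5.6	6.2	9.6	9.2	10.0
West	census_region	81462	24.0	4.5	4.0	5.0	7.6	7.0	8.3
New England	census_division	38543	4.5	4.0	3.6	4.3	6.6	6.1	7.0
Middle Atlantic	census_division	25972	12.2	4.4	4.0	4.8	7.3	6.8	7.8
East North Central	census_division	34376	14.4	6.0	5.6	6.4	10.3	9.7	10.8
West North Central	census_division	63612	6.6	5.6	5.4	5.9	9.3	9.0	9.7
South Atlantic	census_division	59068	20.4	5.4	5.0	5.8	8.6	8.1	9.1
East South Central	census_division	18501	6.1	7.3	6.7	7.8	12.0	11.3	12.7
West South Central	census_division	22553	11.9	6.0	5.4	6.6	10.2	9.4	11.1
Mountain	census_division	50992	7.6	4.3	4.0	4.6	7.3	6.9	7.7
Pacific	census_division	30470	16.4	4.6	3.9	5.3	7.8	6.9	8.8
Metropolitan	locality	236305	85.0	5.0	4.8	5.2	8.4	8.2	8.7
Nonmetropolitan	locality	107782	15.0	6.8	6.5	7.2	10.8	10.4	11.2
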