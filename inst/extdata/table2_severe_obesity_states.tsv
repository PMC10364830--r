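location	self_reported_est	self_reported_ci_low	self_reported_ci_high	corrected_total_est	corrected_total_ci_low	corrected_total_ci_high	corrected_men_est	corrected_men_ci_low	corrected_men_ci_high	corrected_women_est	corrected_women_ci_low	corrected_women_ci_high	sig_above_national
Alabama	7.4	6.5	8.5	12.7	11.5	14.0	8.2	6.8	9.9	16.9	15.1	18.9	TRUE
Alaska	4.9	3.8	6.3	9.2	7.7	11.1	7.8	5.8	10.4	10.9	8.7	13.7	FALSE
Arizona	4.6	4.0	5.3	7.8	7.0	8.6	5.8	4.9	6.9	9.8	8.5	11.2	FALSE
Arkansas	6.5	5.5	7.6	11.8	10.5	13.2	7.6	6.1	9.4	16.1	14.0	18.4	TRUE
California	4.6	3.8	5.7	8.0	6.7	9.4	6.4	4.9	8.4	9.5	7.8	11.6	FALSE
Colorado	3.3	2.9	3.8	5.7	5.2	6.3	3.8	3.2	4.5	7.7	6.8	8.8	FALSE
Connecticut	4.5	3.8	5.3	7.3	6.4	8.3	5.5	4.5	6.9	9.0	7.6	10.7	FALSE
Delaware	6.5	5.4	7.8	10.2	8.9	11.8	8.2	6.4	10.5	12.1	10.2	14.3	TRUE
District of Columbia	4.0	3.1	5.2	7.1	5.9	8.6	3.9	2.6	5.8	10.1	8.1	12.5	FALSE
Florida	4.5	3.7	5.5	6.9	5.9	8.0	5.1	4.1	6.4	8.7	7.1	10.6	FALSE
Georgia	6.4	5.5	7.4	10.2	9.1	11.4	8.5	6.9	10.4	11.9	10.4	13.5	TRUE
Hawaii	3.5	2.9	4.1	6.1	5.4	6.9	5.3	4.3	6.4	6.9	5.9	8.1	FALSE
Idaho	4.4	3.7	5.2	8.1	7.1	9.2	6.4	5.2	7.8	9.9	8.3	11.7	FALSE
Illinois	4.7	3.7	5.8	8.8	7.4	10.4	6.5	5.1	8.4	11.0	8.8	13.6	FALSE
Indiana	6.9	6.2	7.7	11.2	10.4	12.2	8.7	7.6	9.9	13.9	12.5	15.4	TRUE
Iowa	6.4	5.8	7.0	10.6	9.8	11.4	7.7	6.8	8.7	13.7	12.4	15.0	TRUE
Kansas	5.6	5.1	6.2	9.7	9.0	10.5	6.8	5.9	7.7	12.8	11.6	14.1	TRUE
Kentucky	7.8	6.7	9.0	11.8	10.4	13.4	8.4	7.0	10.2	15.2	13.1	17.6	TRUE
Louisiana	7.2	6.2	8.3	12.4	11.0	13.8	8.5	6.8	10.5	16.1	14.2	18.3	TRUE
Maine	5.1	4.4	5.9	8.3	7.5	9.3	6.8	5.8	8.1	9.9	8.6	11.3	FALSE
Maryland	4.9	4.4	5.5	8.0	7.4	8.8	5.5	4.7	6.5	10.6	9.5	11.7	FALSE
Massachusetts	3.3	2.7	4.0	5.5	4.8	6.3	4.3	3.4	5.3	6.8	5.6	8.2	FALSE
Michigan	6.5	5.8	7.3	10.8	9.9	11.9	7.6	6.4	8.9	14.2	12.6	15.9	TRUE
Minnesota	4.5	4.1	5.0	7.8	7.3	8.4	6.4	5.7	7.2	9.4	8.6	10.3	FALSE
Mississippi	7.8	7.0	8.7	13.0	11.9	14.1	8.3	7.0	9.8	17.4	15.8	19.1	TRUE
Missouri	6.6	5.9	7.3	10.4	9.6	11.3	7.2	6.2	8.4	13.7	12.4	15.2	TRUE
Montana	3.9	3.2	4.6	6.9	6.1	7.8	4.7	3.8	5.9	9.2	7.9	10.7	FALSE
Nebraska	5.2	4.7	5.8	8.8	8.1	9.5	5.9	5.1	6.7	11.8	10.6	13.1	FALSE
Nevada	5.0	4.0	6.3	8.1	6.8	9.7	6.5	4.9	8.6	9.7	7.7	12.2	FALSE
New Hampshire	5.0	4.2	5.9	7.9	7.0	9.0	6.0	4.8	7.5	10.0	8.5	11.6	FALSE
New Jersey	3.8	3.4	4.4	6.5	5.8	7.2	5.4	4.6	6.3	7.6	6.6	8.7	FALSE
New Mexico	4.5	3.7	5.4	7.9	6.8	9.1	6.0	4.7	7.5	9.9	8.2	11.9	FALSE
New York	4.0	3.5	4.6	6.8	6.1	7.5	5.1	4.3	6.2	8.5	7.5	9.5	FALSE
North Carolina	5.2	4.4	6.1	9.0	8.0	10.1	6.8	5.5	8.3	11.2	9.8	12.9	FALSE
North Dakota	5.1	4.2	6.2	8.4	7.2	9.8	6.3	5.0	8.0	10.8	8.8	13.2	FALSE
Ohio	6.7	6.1	7.3	11.3	10.5	12.1	7.6	6.7	8.6	14.9	13.7	16.2	TRUE
Oklahoma	7.7	6.8	8.7	11.8	10.6	13.1	8.2	6.9	9.8	15.4	13.6	17.4	TRUE
Oregon	4.4	3.7	5.1	7.4	6.6	8.3	4.9	4.0	6.1	10.0	8.7	11.5	FALSE
Pennsylvania	5.3	4.5	6.1	8.5	7.5	9.6	6.5	5.3	8.0	10.6	9.1	12.2	FALSE
Rhode Island	3.8	3.1	4.7	7.1	6.1	8.3	4.9	3.6	6.5	9.4	7.8	11.2	FALSE
South Carolina	6.8	5.8	7.9	10.1	8.8	11.4	6.2	4.9	7.8	13.8	11.9	16.0	TRUE
South Dakota	4.8	4.0	5.9	7.8	6.6	9.2	6.4	5.0	8.1	9.4	7.3	12.0	FALSE
Tennessee	6.6	5.6	7.7	11.1	9.8	12.5	7.8	6.3	9.6	14.3	12.4	16.5	TRUE
Texas	5.4	4.7	6.4	9.4	8.3	10.6	7.1	5.7	8.8	11.8	10.2	13.6	FALSE
Utah	4.7	4.1	5.2	7.7	7.1	8.5	5.8	5.0	6.7	9.9	8.8	11.1	FALSE
Vermont	3.8	3.2	4.6	6.4	5.6	7.3	5.0	4.0	6.2	7.9	6.7	9.3	FALSE
Virginia	5.4	4.8	6.2	8.8	8.0	9.7	6.4	5.4	7.5	11.3	10.0	12.7	FALSE
Washington	4.4	3.9	4.9	7.2	6.6	7.9	5.4	4.7	6.3	9.1	8.2	10.2	FALSE
West Virginia	8.3	7.4	9.3	13.2	12.1	14.4	10.3	8.9	12.0	16.2	14.5	18.0	TRUE
Wisconsin	5.4	4.5	6.4	9.3	8.1	10.6	6.0	4.8	7.5	12.8	10.8	15.0	FALSE
Wyoming	3.6	2.8	4.4	6.9	5.8	8.2	4.8	3.6	6.2	9.4	7.6	11.6	FALSE
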