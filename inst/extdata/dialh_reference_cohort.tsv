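# Clinical-characteristics counts from a published FAERS analysis of
# drug-induced autoimmune-like hepatitis (5,723 deduplicated reports).
# percent_printed is the percentage as printed; denom is its denominator
# (report count for single-valued variables, total outcome entries for
# the multi-valued outcomes variable).
variable	level	count	percent_printed	denom
sex	female	3498	61.12	5723
sex	male	1641	28.67	5723
sex	unknown	584	10.20	5723
age	<19	243	4.25	5723
age	19~45	999	17.46	5723
age	45~65	1860	32.50	5723
age	65~75	841	14.70	5723
age	>=75	472	8.25	5723
age	unknown	1308	22.86	5723
reporter	Physician	2520	44.03	5723
reporter	Other health-professional	1153	20.15	5723
reporter	Consumer	898	15.69	5723
reporter	Pharmacist	858	14.99	5723
reporter	unknown	266	4.65	5723
reporter	Lawyer	27	0.47	5723
reporter	Registered Nurse	1	0.02	5723
country	other	2931	51.21	5723
country	United States	1490	26.04	5723
country	Germany	396	6.92	5723
country	Japan	321	5.61	5723
country	France	318	5.56	5723
country	United Kingdom	267	4.67	5723
outcome	other serious	4360	54.38	8018
outcome	hospitalization	2573	32.09	8018
outcome	death	448	5.59	8018
outcome	life threatening	404	5.04	8018
outcome	disability	186	2.32	8018
outcome	required intervention	44	0.55	8018
outcome	congenital anomaly	3	0.04	8018
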