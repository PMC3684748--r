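country	location	year	sample_code	region	cluster	membership_prob	n	var_loci	missing_pct	hobs	hexp
Iceland	Northeast coastal	2002	INC02	coastal	Iceland-inshore	0.69	39	841	0.7	0.27	0.27
Iceland	Southwest coastal	2002	ISC02	coastal	Iceland-inshore	0.90	38	845	1.0	0.27	0.27
Iceland	Southwest offshore	2002	ISO02	offshore	East	0.83	39	851	0.8	0.26	0.26
Greenland	Tasiilaq	2010	TAS10	coastal	East	0.69	29	807	13.7	0.28	0.25
Greenland	Offshore East	2010	OEA10	offshore	East	0.96	29	810	6.0	0.27	0.25
Greenland	Offshore South	2010	OSO10	offshore	East	0.96	29	807	11.0	0.28	0.26
Greenland	Danas Banke	1934	DAB34	offshore	East	0.52	31	926	3.2	0.29	0.29
Greenland	Danas Banke	2008	DAB08	offshore	East	0.67	21	857	3.5	0.26	0.27
Greenland	Fyllas Banke	1954	FYB54	offshore	East	0.50	30	891	3.6	0.28	0.28
Greenland	Qaqortoq	1947	QAQ47	coastal	West	0.82	28	914	4.6	0.31	0.32
Greenland	Qaqortoq	2008	QAQ08	coastal	East	0.39	27	854	3.5	0.26	0.27
Greenland	Paamiut	1947	PAA47	coastal	West	0.87	31	917	4.9	0.33	0.31
Greenland	Paamiut	2008	PAA08	coastal	East	0.49	29	850	3.0	0.27	0.27
Greenland	Ameralik	2008	AME08	fjord	Nuuk	0.79	30	891	3.8	0.29	0.30
Greenland	Qorqut	2008	QOR08	fjord	Nuuk	0.76	30	901	3.7	0.30	0.29
Greenland	Kapisillit	1943	KAP43	fjord	Nuuk	0.77	30	894	4.2	0.30	0.29
Greenland	Kapisillit	2008	KAP08	fjord	Nuuk	0.75	30	902	1.5	0.30	0.30
Greenland	Offshore West	2010	OWE10	offshore	West	0.56	39	910	2.1	0.29	0.29
Greenland	Lille Hellefiskebanke	1957	LHB57	offshore	West	0.81	31	912	5.3	0.30	0.31
Greenland	Store Hellefiskebanke	1950	SHB50	offshore	West	0.37	31	909	1.7	0.29	0.30
Greenland	Sisimiut	1932	SIS32	coastal	West	0.99	20	876	7.8	0.33	0.31
Greenland	Sisimiut	1937	SIS37	coastal	West	0.96	31	891	4.8	0.29	0.30
Greenland	Sisimiut	2005	SIS05	coastal	West	0.42	34	919	1.7	0.31	0.31
Greenland	Sisimiut	2010	SIS10	coastal	West	0.50	26	892	13.7	0.34	0.30
Greenland	Ilulissat	1953	ILL53	coastal	West	0.80	30	898	3.8	0.31	0.31
Greenland	Ilulissat	2010	ILL10	coastal	West	0.65	30	902	3.7	0.31	0.30
Greenland	Uummannaq	1945	UMM45	coastal	West	0.73	30	898	3.7	0.31	0.31
Greenland	Uummannaq	2010	UMM10	coastal	West	0.95	25	891	11.1	0.35	0.31
Canada	Gulf of St Lawrence	2008	CAN08	coastal	NA	NA	39	907	1.2	0.36	0.36
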