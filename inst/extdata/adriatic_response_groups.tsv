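taxon	published_group	share_C_pct	share_F_pct	share_FP_pct	fc_filtered_control	fc_phosphate_filtered	borderline
Saccharospirillaceae	I	0.05	2.98	4.45	5.36	1.52	FALSE
Campylobacterales	I	0.04	0.22	0.38	6.75	1.62	FALSE
Polaribacter	I	3.03	0.67	0.70	3.57	1.76	FALSE
Oceanospirillales	I	7.08	5.30	6.90	3.45	1.53	FALSE
Alteromonadales	I	7.27	77.51	77.16	3.07	1.90	FALSE
NS3a marine group	I	0.59	0.31	0.33	2.90	1.63	FALSE
Spongiispira	I	0.05	2.63	3.93	2.74	1.75	FALSE
Rhodospirillales	I	0.14	0.12	0.15	2.2	1.66	FALSE
OM60(NOR5)	I	7.31	0.59	0.54	2.08	1.52	FALSE
Burkholderiales	I	0.78	0.12	0.10	2.02	1.93	FALSE
Other Flavobacteriales	I	1.04	1.03	1.09	2.02	2.16	FALSE
Pirellulales	I	1.45	0.02	0.01	2.05	1.54	FALSE
Cellvibrionales	I	7.79	0.60	0.57	1.82	1.56	FALSE
SAR86	I	0.55	0.18	0.22	1.79	1.54	FALSE
Caulobacterales	I	2.08	0.02	0.02	NA	1.78	FALSE
Flavobacteriales, all	I	32.61	2.18	2.36	1.51	2.63	FALSE
KI89A clade	I	0.34	0.04	0.03	1.49	1.80	FALSE
SAR116	III	1.09	0.24	0.25	1.35	1.49	TRUE
Cytophagales	III	0.24	0.03	0.03	1.13	2.48	FALSE
SAR92	III	0.26	0.00	0.02	1.12	1.75	FALSE
Flavobacteriales, NS groups	III	21.97	1.13	1.24	1.10	2.93	FALSE
Rickettsiales	III	0.11	0.02	0.01	1.04	2.79	FALSE
Bacteriovoracales	III	0.026	0.003	0.001	0.92	2.10	FALSE
SAR11 clade	III	0.97	0.46	0.57	0.90	2.98	FALSE
Thiotrichales	III	0.35	0.04	0.05	0.91	2.86	FALSE
Balneolales	III	1.53	0.10	0.13	0.86	2.51	FALSE
Nereida	II	3.04	8.69	7.98	5.90	1.39	TRUE
Rhodobacterales	II	12.60	12.27	10.71	5.33	1.28	FALSE
Rhizobiales	II	2.60	0.07	0.05	5.12	1.07	FALSE
Sphingomonadales	II	0.61	0.02	0.01	3.64	0.67	FALSE
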