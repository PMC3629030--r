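region	partition	length_bp	S	percent_polymorphism	pi	theta_w
five_prime_utr	all	133	7	5.26	0.01274	0.01055
exon_1	all	609	29	4.76	0.01266	0.01105
exon_1	synonymous	143.83	13	9.04	0.03637	0.02226
exon_1	nonsynonymous	456.17	16	3.51	0.00519	0.00752
intron_1	all	135	5	3.70	0.00478	0.00520
exon_2	all	145	5	3.45	0.00524	0.00789
exon_2	synonymous	33.33	2	6.00	0.01346	0.00686
exon_2	nonsynonymous	110.67	3	2.71	0.00276	0.00827
intron_2	all	88	7	7.95	0.02088	0.01840
exon_3	all	80	3	3.75	0.00225	0.00880
exon_3	synonymous	15.22	1	6.57	0.00292	0.01501
exon_3	nonsynonymous	59.78	2	3.35	0.00296	0.01148
intron_3	all	1676	84	5.01	0.00893	0.01219
exon_4	all	84	6	7.14	0.00714	0.01634
exon_4	synonymous	16.26	3	18.45	0.00651	0.03371
exon_4	nonsynonymous	64.74	3	4.63	0.00735	0.01078
intron_4	all	120	17	14.17	0.02391	0.02407
exon_5	all	75	4	5.33	0.00294	0.01220
exon_5	synonymous	17.67	2	13.32	0.00743	0.02589
exon_5	nonsynonymous	57.33	2	3.49	0.00155	0.00798
intron_5	all	327	19	5.81	0.01224	0.01329
exon_6	all	93	2	2.15	0.00305	0.00497
exon_6	synonymous	21.33	2	9.38	0.01316	0.02144
exon_6	nonsynonymous	68.67	0	0	0	0
intron_6	all	228	17	7.46	0.01462	0.01759
exon_7	all	207	13	6.28	0.00319	0.01436
exon_7	synonymous	44.38	5	11.27	0.00687	0.02577
exon_7	nonsynonymous	159.62	8	5.01	0.00223	0.01146
three_prime_utr	all	374	25	6.68	0.01484	0.01720
total_silent	all	3269.78	209	8.93	0.01228	0.01420
total	synonymous	295.78	28	9.47	0.02210	0.02088
total	nonsynonymous	976.22	34	3.48	0.00385	0.00820
total	all	4374	243	5.56	0.01033	0.01280
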