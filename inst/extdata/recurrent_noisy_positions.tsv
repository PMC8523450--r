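position	rcrs_base	second_variant	numt	mean_s1	sd_s1	mean_s2	sd_s2
309	C	DEL	TRUE	37.76	23.81	36.18	5.69
315	C	INS	FALSE	77.40	10.21	81.84	4.08
438	C	DEL	FALSE	86.36	6.83	87.33	4.34
498	C	DEL	FALSE	84.75	2.13	82.32	2.74
937	T	DEL	FALSE	88.09	6.60	86.77	3.67
1296	A	DEL	TRUE	85.84	6.01	81.91	5.73
2135	A	DEL	FALSE	83.75	4.54	83.21	5.95
5287	A	DEL	TRUE	85.76	6.11	86.34	1.48
5752	A	DEL	TRUE	75.32	14.18	73.43	9.89
7402	C	DEL	FALSE	74.03	6.31	77.93	9.17
7513	T	DEL	FALSE	72.39	13.67	72.28	9.02
8249	G	INS	FALSE	56.47	14.13	61.26	4.32
8252	C	G	FALSE	84.66	4.62	84.34	5.54
8254	C	DEL	FALSE	60.31	5.32	57.51	5.16
8255	G	DEL	TRUE	75.14	11.57	79.94	4.71
8256	T	DEL	FALSE	62.78	10.49	58.67	5.08
8962	A	DEL	FALSE	83.35	5.73	83.22	5.42
9100	A	G	FALSE	78.83	4.36	81.09	3.85
10151	A	DEL	FALSE	87.12	5.91	85.59	4.16
11038	A	DEL	FALSE	87.17	5.73	87.41	3.10
12425	A	DEL	FALSE	66.95	12.42	76.17	4.26
13237	A	DEL	TRUE	88.15	4.95	89.89	2.88
13758	C	DEL	FALSE	54.32	6.28	58.76	4.84
14510	A	DEL	FALSE	83.97	7.57	84.23	5.51
14754	C	DEL	TRUE	81.30	12.77	79.64	5.44
14774	C	DEL	TRUE	87.38	10.76	86.89	3.94
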