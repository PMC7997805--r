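site_id	d6_pos_grch37	d6_pos_grch38	d7_pos_grch37	d7_pos_grch38	d6_base	d7_base	segment
1	42522161	42126159	42535361	42139359	C	G	flank3
2	42522196	42126194	42535396	42139394	G	T	flank3
3	42522231	42126229	42535431	42139429	T	A	flank3
4	42522266	42126264	42535466	42139464	A	C	flank3
5	42522300	42126298	42535500	42139498	C	G	flank3
6	42522335	42126333	42535535	42139533	G	T	flank3
7	42522370	42126368	42535570	42139568	T	A	flank3
8	42522405	42126403	42535605	42139603	A	C	flank3
9	42522440	42126438	42535640	42139638	C	G	flank3
10	42522561	42126559	42535761	42139759	G	T	exon9
11	42522585	42126583	42535785	42139783	T	A	exon9
12	42522608	42126606	42535808	42139806	A	C	exon9
13	42522633	42126631	42535833	42139831	C	G	exon9
14	42522656	42126654	42535856	42139854	G	T	exon9
15	42522680	42126678	42535880	42139878	T	A	exon9
16	42522703	42126701	42535903	42139901	A	C	exon9
17	42522727	42126725	42535927	42139925	C	G	exon9
18	42522751	42126749	42535951	42139949	G	T	exon9
19	42522775	42126773	42535975	42139973	T	A	exon9
20	42522798	42126796	42535998	42139996	A	C	exon9
21	42522822	42126820	42536022	42140020	C	G	exon9
22	42522943	42126941	42536143	42140141	G	T	exon8
23	42522974	42126972	42536174	42140172	T	A	exon8
24	42523005	42127003	42536205	42140203	A	C	exon8
25	42523035	42127033	42536235	42140233	C	G	exon8
26	42523066	42127064	42536266	42140264	G	T	exon8
27	42523097	42127095	42536297	42140295	T	A	exon8
28	42523128	42127126	42536328	42140326	A	C	exon8
29	42523159	42127157	42536359	42140357	C	G	exon8
30	42523189	42127187	42536389	42140387	G	T	exon8
31	42523220	42127218	42536420	42140418	T	A	exon8
32	42523251	42127249	42536451	42140449	A	C	exon8
33	42523372	42127370	42536572	42140570	C	G	exon7
34	42523403	42127401	42536603	42140601	G	T	exon7
35	42523434	42127432	42536634	42140632	T	A	exon7
36	42523464	42127462	42536664	42140662	A	C	exon7
37	42523495	42127493	42536695	42140693	C	G	exon7
38	42523526	42127524	42536726	42140724	G	T	exon7
39	42523557	42127555	42536757	42140755	T	A	exon7
40	42523588	42127586	42536788	42140786	A	C	exon7
41	42523618	42127616	42536818	42140816	C	G	exon7
42	42523649	42127647	42536849	42140847	G	T	exon7
43	42523680	42127678	42536880	42140878	T	A	exon7
44	42523801	42127799	42537001	42140999	A	C	exon6
45	42523823	42127821	42537023	42141021	C	G	exon6
46	42523845	42127843	42537045	42141043	G	T	exon6
47	42523867	42127865	42537067	42141065	T	A	exon6
48	42523889	42127887	42537089	42141087	A	C	exon6
49	42523910	42127908	42537110	42141108	C	G	exon6
50	42523932	42127930	42537132	42141130	G	T	exon6
51	42523954	42127952	42537154	42141152	T	A	exon6
52	42523976	42127974	42537176	42141174	A	C	exon6
53	42523998	42127996	42537198	42141196	C	G	exon6
54	42524020	42128018	42537220	42141218	G	T	exon6
55	42524141	42128139	42537341	42141339	T	A	exon5
56	42524178	42128176	42537378	42141376	A	C	exon5
57	42524215	42128213	42537415	42141413	C	G	exon5
58	42524251	42128249	42537451	42141449	G	T	exon5
59	42524288	42128286	42537488	42141486	T	A	exon5
60	42524325	42128323	42537525	42141523	A	C	exon5
61	42524362	42128360	42537562	42141560	C	G	exon5
62	42524399	42128397	42537599	42141597	G	T	exon5
63	42524435	42128433	42537635	42141633	T	A	exon5
64	42524472	42128470	42537672	42141670	A	C	exon5
65	42524509	42128507	42537709	42141707	C	G	exon5
66	42524630	42128628	42537830	42141828	G	T	exon4
67	42524660	42128658	42537860	42141858	T	A	exon4
68	42524690	42128688	42537890	42141888	A	C	exon4
69	42524720	42128718	42537920	42141918	C	G	exon4
70	42524750	42128748	42537950	42141948	G	T	exon4
71	42524780	42128778	42537980	42141978	T	A	exon4
72	42524810	42128808	42538010	42142008	A	C	exon4
73	42524840	42128838	42538040	42142038	C	G	exon4
74	42524870	42128868	42538070	42142068	G	T	exon4
75	42524900	42128898	42538100	42142098	T	A	exon4
76	42524930	42128928	42538130	42142128	A	C	exon4
77	42525051	42129049	42538251	42142249	C	G	exon3
78	42525086	42129084	42538286	42142284	G	T	exon3
79	42525121	42129119	42538321	42142319	T	A	exon3
80	42525157	42129155	42538357	42142355	A	C	exon3
81	42525192	42129190	42538392	42142390	C	G	exon3
82	42525227	42129225	42538427	42142425	G	T	exon3
83	42525262	42129260	42538462	42142460	T	A	exon3
84	42525297	42129295	42538497	42142495	A	C	exon3
85	42525333	42129331	42538533	42142531	C	G	exon3
86	42525368	42129366	42538568	42142566	G	T	exon3
87	42525403	42129401	42538603	42142601	T	A	exon3
88	42525524	42129522	42538724	42142722	A	C	exon2
89	42525586	42129584	42538786	42142784	C	G	exon2
90	42525647	42129645	42538847	42142845	G	T	exon2
91	42525709	42129707	42538909	42142907	T	A	exon2
92	42525771	42129769	42538971	42142969	A	C	exon2
93	42525832	42129830	42539032	42143030	C	G	exon2
94	42525894	42129892	42539094	42143092	G	T	exon2
95	42525955	42129953	42539155	42143153	T	A	exon2
96	42526017	42130015	42539217	42143215	A	C	exon2
97	42526079	42130077	42539279	42143277	C	G	exon2
98	42526140	42130138	42539340	42143338	G	T	exon2
99	42526202	42130200	42539402	42143400	T	A	exon2
100	42526323	42130321	42539523	42143521	A	C	exon1
101	42526362	42130360	42539562	42143560	C	G	exon1
102	42526401	42130399	42539601	42143599	G	T	exon1
103	42526440	42130438	42539640	42143638	T	A	exon1
104	42526479	42130477	42539679	42143677	A	C	exon1
105	42526518	42130516	42539718	42143716	C	G	exon1
106	42526557	42130555	42539757	42143755	G	T	exon1
107	42526596	42130594	42539796	42143794	T	A	exon1
108	42526635	42130633	42539835	42143833	A	C	exon1
109	42526674	42130672	42539874	42143872	C	G	exon1
110	42526714	42130712	42539914	42143912	G	T	exon1
111	42526752	42130750	42539952	42143950	T	A	exon1
112	42526873	42130871	42540073	42144071	A	C	flank5
113	42526929	42130927	42540129	42144127	C	G	flank5
114	42526985	42130983	42540185	42144183	G	T	flank5
115	42527040	42131038	42540240	42144238	T	A	flank5
116	42527096	42131094	42540296	42144294	A	C	flank5
117	42527152	42131150	42540352	42144350	C	G	flank5
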