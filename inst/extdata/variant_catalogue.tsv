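g_label	ref	alt	type	segment	in_homology	d6_pos_grch37	d6_pos_grch38	d7_mirror_grch37	d7_mirror_grch38
g.5C>G	C	G	snv	exon1	FALSE	42526808	42130806		
g.19G>A	G	A	snv	exon1	FALSE	42526794	42130792		
g.31G>A	G	A	snv	exon1	FALSE	42526782	42130780		
g.77G>A	G	A	snv	exon1	FALSE	42526736	42130734		
g.82C>T	C	T	snv	exon1	FALSE	42526731	42130729		
g.100C>T	C	T	snv	exon1	FALSE	42526713	42130711		
g.125G>A	G	A	snv	exon1	FALSE	42526688	42130686		
g.137insT	A	AT	ins	exon1	FALSE	42526676	42130674		
g.237A>C	A	C	snv	exon1	FALSE	42526576	42130574		
g.883G>C	G	C	snv	exon2	TRUE	42525930	42129928	42539130	42143128
g.939C>T	C	T	snv	exon2	TRUE	42525874	42129872	42539074	42143072
g.1012G>A	G	A	snv	exon2	TRUE	42525801	42129799	42539001	42142999
g.1022C>T	C	T	snv	exon2	TRUE	42525791	42129789	42538991	42142989
g.1513C>T	C	T	snv	exon3	FALSE	42525300	42129298		
g.1598A>G	A	G	snv	exon3	FALSE	42525215	42129213		
g.1611T>A	T	A	snv	exon3	FALSE	42525202	42129200		
g.1660G>A	G	A	snv	exon3	FALSE	42525153	42129151		
g.1704C>G	C	G	snv	exon3	FALSE	42525109	42129107		
g.1708delT	AT	A	del	exon3	FALSE	42525105	42129103		
g.1716G>A	G	A	snv	exon3	FALSE	42525097	42129095		
g.1759G>A	G	A	snv	exon3	FALSE	42525054	42129052		
g.1847G>A	G	A	snv	exon4	FALSE	42524966	42128964		
g.1863insTTT	A	ATTT	ins	exon4	FALSE	42524950	42128948		
g.2225C>T	C	T	snv	exon4	FALSE	42524588	42128586		
g.2549delA	CA	C	del	exon5	FALSE	42524264	42128262		
g.2573insC	G	GC	ins	exon5	FALSE	42524240	42128238		
g.2616delAAG	TAAG	T	del	exon5	FALSE	42524197	42128195		
g.2851C>T	C	T	snv	exon6	TRUE	42523962	42127960	42537162	42141160
g.2936A>C	A	C	snv	exon6	TRUE	42523877	42127875	42537077	42141075
g.2939G>A	G	A	snv	exon6	TRUE	42523874	42127872	42537074	42141072
g.2989G>A	G	A	snv	exon6	TRUE	42523824	42127822	42537024	42141022
g.3184G>A	G	A	snv	exon7	FALSE	42523629	42127627		
g.3201C>T	C	T	snv	exon7	FALSE	42523612	42127610		
g.3254T>C	T	C	snv	exon7	FALSE	42523559	42127557		
g.3877G>C	G	C	snv	exon8	FALSE	42522936	42126934		
g.4042G>A	G	A	snv	exon9	FALSE	42522771	42126769		
g.4181G>C	G	C	snv	exon9	FALSE	42522632	42126630		
g.4222G>C	G	C	snv	exon9	FALSE	42522591	42126589		
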