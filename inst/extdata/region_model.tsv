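build	chrom	name	start	end
GRCh38	chr22	d6	42126499	42130810
GRCh38	chr22	d7	42139699	42144010
GRCh38	chr22	rep6	42123192	42125972
GRCh38	chr22	rep7	42135344	42138124
GRCh38	chr22	spacer	42138124	42139676
GRCh38	chr22	d6_exon1	42130612	42130810
GRCh38	chr22	d6_exon2	42129738	42129909
GRCh38	chr22	d6_exon3	42129033	42129185
GRCh38	chr22	d6_exon4	42128784	42128944
GRCh38	chr22	d6_exon5	42128174	42128350
GRCh38	chr22	d6_exon6	42127842	42127983
GRCh38	chr22	d6_exon7	42127447	42127634
GRCh38	chr22	d6_exon8	42127008	42127171
GRCh38	chr22	d6_exon9	42126499	42126752
GRCh38	chr22	d7_exon1	42143812	42144010
GRCh38	chr22	d7_exon2	42142938	42143109
GRCh38	chr22	d7_exon3	42142233	42142385
GRCh38	chr22	d7_exon4	42141984	42142144
GRCh38	chr22	d7_exon5	42141374	42141550
GRCh38	chr22	d7_exon6	42141042	42141183
GRCh38	chr22	d7_exon7	42140647	42140834
GRCh38	chr22	d7_exon8	42140208	42140371
GRCh38	chr22	d7_exon9	42139699	42139952
GRCh38	chr22	homology1	42127800	42128300
GRCh38	chr22	homology2	42129650	42130050
GRCh37	chr22	d6	42522501	42526812
GRCh37	chr22	d7	42535701	42540012
GRCh37	chr22	rep6	42519194	42521974
GRCh37	chr22	rep7	42531346	42534126
GRCh37	chr22	spacer	42534126	42535678
GRCh37	chr22	d6_exon1	42526614	42526812
GRCh37	chr22	d6_exon2	42525740	42525911
GRCh37	chr22	d6_exon3	42525035	42525187
GRCh37	chr22	d6_exon4	42524786	42524946
GRCh37	chr22	d6_exon5	42524176	42524352
GRCh37	chr22	d6_exon6	42523844	42523985
GRCh37	chr22	d6_exon7	42523449	42523636
GRCh37	chr22	d6_exon8	42523010	42523173
GRCh37	chr22	d6_exon9	42522501	42522754
GRCh37	chr22	d7_exon1	42539814	42540012
GRCh37	chr22	d7_exon2	42538940	42539111
GRCh37	chr22	d7_exon3	42538235	42538387
GRCh37	chr22	d7_exon4	42537986	42538146
GRCh37	chr22	d7_exon5	42537376	42537552
GRCh37	chr22	d7_exon6	42537044	42537185
GRCh37	chr22	d7_exon7	42536649	42536836
GRCh37	chr22	d7_exon8	42536210	42536373
GRCh37	chr22	d7_exon9	42535701	42535954
GRCh37	chr22	homology1	42523802	42524302
GRCh37	chr22	homology2	42525652	42526052
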