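snp_id	snp_location	nearest_gene	chrom	start	end
rs3767137	intronic	HSPG2	chr1	21834230	21841817
rs1800255	exonic	COL3A1	chr2	188976887	189003156
rs1429412	intergenic	ANKRD44	chr2	197283467	197358397
rs700651	intronic	BOLL	chr2	197676674	197766990
rs6841581	intergenic	EDNRA	chr4	147444187	147493499
rs251124	intronic	VCAN	chr5	83509605	83530435
rs4628172	intronic	AGMO	chr7	15454259	15466904
rs1800796	intronic	IL6	chr7	22726627	22732119
rs42524	exonic	COL1A2	chr7	94413927	94420044
rs10958409	intergenic	NA	chr8	54397171	54415556
rs9298506	intergenic	NA	chr8	54509054	54549764
rs2891168	intronic	CDKN2B-AS1	chr9	22072265	22125504
rs10757278	intergenic	CDKN2B-AS1	chr9	22077086	22125504
rs6538595	intronic	FGD6	chr12	95095355	95123067
rs4934	exonic	SERPINA3	chr14	94612340	94614466
rs1132274	exonic	RRBP1	chr20	17613385	17619469
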