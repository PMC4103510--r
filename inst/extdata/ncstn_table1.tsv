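snp_id	utr_name	position	end	polymorphism	mirna_name	seed_region	raw_reads
rs10059	NCSTN_3UTR	18	18	C/T	hsa-miR-31	Y	0
rs41266889	NCSTN_3UTR	196	196	C/T	hsa-miR-3153	Y	0
rs180769907	NCSTN_3UTR	360	360	A/T	hsa-miR-1226*	Y	0
rs180769907	NCSTN_3UTR	360	360	A/T	hsa-miR-608	N	0
rs180769907	NCSTN_3UTR	360	360	A/T	hsa-miR-92a*	N	0
rs1043230	NCSTN_3UTR	367	367	C/A	hsa-miR-92a-2*	Y	0
rs1043230	NCSTN_3UTR	367	367	C/A	hsa-miR-4298	N	0
rs1043329	NCSTN_3UTR	460	460	C/T	hsa-miR-24	N	150
rs141849450	NCSTN_3UTR	515	516	delCA	hsa-miR-455-5p	Y	95
rs34629439	NCSTN_3UTR	582	582	delT	hsa-miR-1301	N	45
rs34629439	NCSTN_3UTR	582	582	delT	hsa-miR-590-5p	N	11
rs34629439	NCSTN_3UTR	582	582	delT	hsa-miR-27b*	N	23
rs34629439	NCSTN_3UTR	582	582	delT	hsa-miR-582-5p	N	15
rs34629439	NCSTN_3UTR	582	582	delT	hsa-miR-656	N	107
rs113810300	NCSTN_3UTR	623	623	T/G	hsa-miR-1252	Y	0
rs113810300	NCSTN_3UTR	623	623	T/G	hsa-miR-3125	Y	0
rs113810300	NCSTN_3UTR	623	623	T/G	hsa-miR-340	Y	1708
rs113810300	NCSTN_3UTR	623	623	T/G	hsa-miR-142-5p	Y	20
rs113810300	NCSTN_3UTR	623	623	T/G	hsa-miR-186	Y	1209
rs113810300	NCSTN_3UTR	623	623	T/G	hsa-miR-3121	N	0
rs113810300	NCSTN_3UTR	623	623	T/G	hsa-miR-4311	N	0
rs71719087	NCSTN_3UTR	638	639	delAT	hsa-miR-3145	Y	0
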