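accession	description	total_peptides	quantified_peptides	mean_reference	mean_test	p_value	ratio
Gi|86262157|ref|NP_808386.2|	Hypothetical protein LOC239796	4	3	0.00343	0.00155	0.00037	0.45091
Gi|124486588|ref|NP_001074475.1|	Sickle tail protein isoform c	28	28	0.05906	0.02017	0.00154	0.34160
Gi|40254129|ref|NP_258435.2|	Armadillo repeat protein deleted in velo-cardio-facial syndrome homolog	17	17	0.06524	0.05290	0.01504	0.81088
Gi|6755368|ref|NP_035426.1|	40S Ribosomal protein S18	5	5	0.01326	0.00710	0.01607	0.53595
Gi|31982755|ref|NP_035831.2|	Vimentin	11	8	0.00262	0.00749	0.01611	2.85760
Gi|31542151|ref|NP_038827.2|	Arginyl-tRNA-protein transferase 1 isoform 1	8	8	0.03619	0.06278	0.02867	1.73447
Gi|112807186|ref|NP_766307.2|	GCN1 general control of amino acid synthesis 1-like 1	2	2	0.00068	0.00027	0.02990	0.40295
Gi|110225370|ref|NP_031488.2|	Adenomatosus polyposis coli protein (APC)	35	35	0.05596	0.09804	0.03139	1.75192
Gi|79750409|ref|NP_075025.2|	Hamartin	7	7	0.00687	0.01120	0.03649	1.63012
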