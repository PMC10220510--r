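lineage	gene_id	gene_name	mutation	mutation_type	description	cohort	ci_fitness	ci_medium	ci_rhizosphere	ci_nodulation	gain_proliferation	phenotypes	g_score	p_adj
B	RSp0595		P132P	synonymous	Putative N-acyl-homoserine lactonase	CoB1	77	1	1	5.2	1.6	Nod+	2.80	1
B	RSc1598		P455L	nonsynonymous	Transmembrane sensor histidine kinase	CoB2	24.2	1	1.4	4.7	6.4	Nod+ Pro+	1.04	1
B	RSp0788		E225K	nonsynonymous	Carbamoyl-transferase	CoB3	1.9	1	1.1	2	1.2	Nod+	-0.09	1
B	RSp1417		S417L	nonsynonymous	Multidrug efflux transmembrane protein	CoB3	1.6	0.8	1.4	3.9	0.9	Nod+	12.47	2.58E-04
B	RSp1590		S153L	nonsynonymous	FAD-dependent oxireductase	CoB3	6.3	1	0.9	2.4	0.6	Nod+	4.10	1
B	up115-RSc0965		G/A	intergenic	Unknown function, negative regulator of efpR expression	CoB6	31.1	0.9	2.9	8.2	2.6	Rhizo+ Nod+ Pro+		
B	RSc0539	rhlE1	L368L	synonymous	ATP-dependent RNA helicase protein	CoB7	46.2	1.1	4	28.2	2.4	Rhizo+ Nod+ Pro+	2.88	1
B	RSc0243		L213L	synonymous	LysR-type transcription regulator protein	CoB10	3	1.3	1.4	3.9	1.1	Rhizo+ Nod+	1.16	1
B	RSp1116		I32I;L33F	synonymous	Putative low specificity L-threonine aldolase	CoB10	2.1	1.2	1.2	2.1	0.9	Nod+	0.84	1
B	up8-RSp1469		C/T	intergenic	Putative tyrosine-specific protein phosphatase	CoB10	2.1	0.9	1	2	1.0	Nod+		
B	pRALTA_0230		G242E	nonsynonymous	Putative ATP-dependent DNA helicase	CoB10	1.5	1.5	1.5	2.1	0.9	Nod+	6.34	1
B	pRALTA_0552		I100I	synonymous	Pseudogene, putative membrane bound hydrogenase	CoB10	2.9	1.2	1.4	2.3	0.8	Nod+		
G	RSc1097	efpR	E66K	nonsynonymous	Transcriptional regulator	CoG1	212.1	1.3	4	35	3.7	Rhizo+ Nod+ Pro+	3.17	1
G	RSc1982		I100I	synonymous	DNA methyltransferase	CoG2	3.3	3.1	1.3	4.0	0.7	Nod+	1.44	1
G	RSc1164	ppiB	Q112*	nonsense	Peptyl-prolyl-cis/trans-isomerase	CoG4	24.5	1	1.0	5.0	1.4	Nod+	2.26	1
G	RSc2277		V321G	nonsynonymous	Putative transporter protein	CoG4	133.9	9.3	10.1	58	2.5	Nod+ Pro+	36.95	4.68E-50
G	RSc0194		S102F	nonsynonymous	Zinc-dependent alcohol dehydrogenase	CoG13	5.5	1.1	1.6	3.1	1.4	Nod+	4.67	1
G	RSc1633	phbB	S38F	nonsynonymous	Acetoacetyl-CoA reductase	CoG13	7.9	2	2.1	3.3	1.7	Rhizo+ Nod+ Pro+	1.62	1
G	RSp0741	tssJ	I157N	nonsynonymous	Type VI secretion system, lipoprotein TssJ	CoG13	6.7	1	1.1	2.9	1.7	Nod+	6.99	1
G	RSp0574		L15L	synonymous	Hypothetical protein	CoG15	3.2	1.1	1.3	2.1	1.6	Nod+ Pro+	4.36	1
G	RSp0587		P84P	synonymous	Putative signal peptide hypothetical protein	CoG15	2	1.1	0.8	2.6	1.3	Nod+	28.74	1.04E-46
G	RSp0759		F91F;P92S	synonymous	Putative type VI secretion-associated protein	CoG15	5.4	0.7	0.9	2.5	1.4	Nod+	1.00	1
G	RSp0769		F416S	nonsynonymous	Putative type VI secretion-associated protein	CoG15	6.3	1.1	1.3	1.6	1.8	Nod+ Pro+	17.20	3.98E-10
G	up116-RSp0780		C/T	intergenic	Hypothetical protein	CoG15	2.5	1.1	1.1	3	1.1	Nod+		
G	RSp1422		G1298E	nonsynonymous	Nonribosomal peptide synthase	CoG15	2	1.2	1.2	2.4	1.6	Nod+	18.28	2.79E-03
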