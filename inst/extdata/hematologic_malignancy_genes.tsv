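symbol	association
TCL1A	T-cell leukemia/lymphoma; AKT co-activator, overexpressed in T/B-cell malignancies
JAK2	myeloproliferative neoplasms
DNMT3A	clonal hematopoiesis; AML
TET2	clonal hematopoiesis; myeloid malignancies
ASXL1	clonal hematopoiesis; MDS/AML
RUNX1	familial platelet disorder with AML predisposition
TP53	therapy-related myeloid neoplasms; Li-Fraumeni
FLT3	AML
NPM1	AML
MYC	Burkitt lymphoma; aggressive B-cell lymphoma
BCL2	follicular lymphoma
CCND1	mantle cell lymphoma
ATM	chronic lymphocytic leukemia
NRAS	juvenile myelomonocytic leukemia; AML
KRAS	juvenile myelomonocytic leukemia
IDH2	AML
SF3B1	MDS with ring sideroblasts; CLL
SRSF2	MDS/CMML
CALR	essential thrombocythemia; myelofibrosis
MPL	myeloproliferative neoplasms
CEBPA	familial AML
EZH2	lymphoma; MDS
BCOR	MDS/AML
STAG2	MDS/AML
U2AF1	MDS
WT1	AML
KIT	core-binding-factor AML; mastocytosis
GATA2	GATA2 deficiency with MDS/AML predisposition
ETV6	thrombocytopenia with leukemia predisposition
IKZF1	B-cell acute lymphoblastic leukemia
PAX5	B-cell acute lymphoblastic leukemia
MYD88	Waldenstrom macroglobulinemia; DLBCL
CXCR4	Waldenstrom macroglobulinemia
BTK	chronic lymphocytic leukemia (therapy resistance)
NOTCH1	T-cell acute lymphoblastic leukemia; CLL
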