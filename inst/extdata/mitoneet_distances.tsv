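# Metal-to-proton distances of the cluster-binding residues of oxidized
# mitoNEET (PDB 2QD0 numbering), transcribed once from the published
# distance-based assignment table. fe_label is the coordinating iron as
# reported there (Cys-72/Cys-74 bind Fe1; Cys-83/His-87 bind Fe2).
# bonds = covalent bonds from the iron through the coordinating ligand atom;
# ring = proton attached to the coordinating imidazole ring.
chain	resnum	resname	atom	fe_label	r_angstrom	bonds	ring
A	72	CYS	HN	FE1	5.54	5	FALSE
A	72	CYS	HA	FE1	3.21	4	FALSE
A	72	CYS	HB2	FE1	3.47	3	FALSE
A	72	CYS	HB3	FE1	4.35	3	FALSE
A	74	CYS	HN	FE1	3.54	5	FALSE
A	74	CYS	HA	FE1	4.90	4	FALSE
A	74	CYS	HB2	FE1	4.25	3	FALSE
A	74	CYS	HB3	FE1	3.27	3	FALSE
A	83	CYS	HN	FE2	5.61	5	FALSE
A	83	CYS	HA	FE2	3.39	4	FALSE
A	83	CYS	HB2	FE2	3.33	3	FALSE
A	83	CYS	HB3	FE2	4.32	3	FALSE
A	87	HIS	HN	FE2	3.16	6	FALSE
A	87	HIS	HA	FE2	4.99	5	FALSE
A	87	HIS	HB2	FE2	4.39	4	FALSE
A	87	HIS	HB3	FE2	2.98	4	FALSE
A	87	HIS	HE1	FE2	3.06	3	TRUE
A	87	HIS	HNE2	FE2	4.94	4	TRUE
A	87	HIS	HD2	FE2	5.18	4	TRUE
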