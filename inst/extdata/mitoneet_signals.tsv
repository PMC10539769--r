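# Hyperfine 1H peak table of oxidized [Fe2S2]2+ mitoNEET, 600 MHz.
# Transcribed once from the published shift/linewidth table; linewidths at 293 K.
# Proposed assignments use PDB 2QD0 residue numbering.
label	T_kelvin	shift_ppm	linewidth_hz	exchangeable	assignment
A	283	53.8	2700	FALSE	HIS-87-HD2
A	293	54.4	2700	FALSE	HIS-87-HD2
B	283	46.8	2500	TRUE	HIS-87-HNE2
B	293	47.3	2500	TRUE	HIS-87-HNE2
C	283	43.4	2300	FALSE	CYS-83-HB3
C	293	43.9	2300	FALSE	CYS-83-HB3
D	283	34.1	1800	FALSE	CYS-74-HB2
D	293	34.3	1800	FALSE	CYS-74-HB2
E	283	25.7	1500	FALSE	CYS-72-HB3
E	293	25.9	1500	FALSE	CYS-72-HB3
HN1	283	13.6	150	TRUE	NA
HN1	293	13.5	150	TRUE	NA
HN2	283	12.08	200	TRUE	NA
HN2	293	12.02	200	TRUE	NA
HN3	283	11.39	120	TRUE	NA
HN3	293	11.35	120	TRUE	NA
F	283	10.52	250	FALSE	CYS-74-HA/HIS-87-HB2
F	293	10.61	250	FALSE	CYS-74-HA/HIS-87-HB2
HN4	283	10.15	70	TRUE	GLU-38-HN
HN4	293	10.15	70	TRUE	GLU-38-HN
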