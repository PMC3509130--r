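spectrum_id	run_id	sample_id	peptide	prev_aa	next_aa	charge	xcorr	deltcn	ppm_error	protein_ids	is_decoy
psm01	r1	s1	EEEFFFR	K	H	2	3.00	0.10	2.0	protA1	FALSE
psm02	r1	s1	MAAAGGGK	-	E	2	2.80	0.12	-1.5	protA1;protA2	FALSE
psm03	r1	s1	HHHIIIK	R	-	2	2.60	0.15	0.5	protA1;protB1	FALSE
psm04	r1	s1	EEEFFFR	K	H	2	2.49	0.10	0.0	protA1	FALSE
psm05	r2	s1	EEEFFFR	K	H	2	3.10	0.10	10.1	protA1	FALSE
psm06	r2	s1	LLLMMMR	K	N	1	1.80	0.05	3.0	protB1	FALSE
psm07	r2	s1	NNNQQQK	R	-	3	3.50	0.20	-9.8	protB1	FALSE
psm08	r3	s2	FFFEEEK	R	G	2	2.90	0.11	1.0	rev_protA1	TRUE
psm09	r3	s2	EEEYFFR	K	H	2	3.20	0.18	-2.0	protA2	FALSE
psm10	r3	s2	EEFFFR	E	H	2	3.00	0.10	0.0	protA1	FALSE
psm11	r4	s2	VVVTTTR	K	S	2	2.70	0.09	4.0	protC1	FALSE
psm12	r4	s2	SSSEEEK	R	-	3	3.40	0.22	0.0	protC1	FALSE
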