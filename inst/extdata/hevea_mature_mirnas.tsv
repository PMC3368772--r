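name	accession	mature_sequence	printed_length	star_support	precursor_length	source	set
HbmiRn1	acc_584359	CAGGAACUGGUAUCAACCCAGC	22	nd	130	CL1Contig1853_r1	novel
HbmiRn2	acc_495109	UAUUGUAGAAAUUUUCAGGAUC	22	nd	116	CL1Contig490_r1	novel
HbmiRn3	acc_185377	UAAUGGGCUCUGCAUAGAUGG	21	yes:3	108	CL27Contig1_r1	novel
HbmiRn4	acc_108425	UUGCAUAUCUCAGGAGCUUCA	21	yes:4	214	CL19922Contig1_r1	novel
HbmiRn5	acc_644211	AAACGGCUACCACAUCCAA	19	nd	87	FYGXE6I01B755W_r1	novel
HbmiRn6	acc_501419	UAGGAUGUAGAAGAGCAUAA	20	nd	90	F5VNCTM02H9XL3_r1	novel
HbmiRn7	acc_35715	UAGUUUGUUUGAUGGUAUC	19	nd	113	FYGXE6I01EKFYA_r1	novel
HbmiRn8	acc_246127	GAUUGACAGACUGAGAGCUC	20	yes:16	93	FYGXE6I01B7GPL_r1	novel
HbmiRn9	acc_103082	UUUAUGAAAGACGAACAACUG	21	yes:6	87	CL1Contig2798_r1	novel
HbmiR156	acc_462135	UUGACAGAAGAUAGAGAGC	19	yes:10	119	FYGXE6I01DJH4X_r1	conserved
HbmiR159	acc_17403	UUUGGAUUGAAGGGAGCUCUA	21	yes:5	221	GETTCZF01AWUSL_r1	conserved
HbmiR166	acc_28021	UCGGACCAGGCUUCAUUCC	19	yes:14	127	CL2671Contig1_r1	conserved
HbmiR166	acc_150486	UCGGACCAGGCUUCAUUCCCCC	22	yes:14	120	CL1Contig15359_r1	conserved
HbmiR319	acc_19786	UUGGACUGAAGGGAGCUCCCU	21	yes:7	221	FRZQES201D34W3_r1	conserved
HbmiR396	acc_112787	UUCCACAGCUUUCUUGAACUG	21	yes:15	154	CL1Contig13811_r1	conserved
HbmiR408	acc_393516	AAGACUGGGAACAGGCAGAGCA	22	yes:294	128	FYGXE6I01CVDV9_r1	conserved
HbmiR408	acc_39581	ACUGGGAACAGGCAGAGCAUGA	22	yes:294	120	CL3908contig1_r1	conserved
HbmiR476	acc_508145	UAAUCCUUCUUUGCAAAGUC	20	yes:1	126	CL1Contig11471_r1	conserved
HbmiR2910	acc_251816	GAGCGAUUUGUCUGGUUAAUC	21	yes:5	126	FYGXE6I01EDXGX_r1	conserved
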