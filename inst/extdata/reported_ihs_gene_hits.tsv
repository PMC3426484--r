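sub_pathway	gene	continental_group	p_value	corrected_p
Precursor Biosynthesis	ALG12	MENA	3e-10	4.2e-09
Precursor Biosynthesis	ALG12	EUR	1e-10	1.4e-09
Precursor Biosynthesis	ALG12	EASIA	5e-11	7.0e-10
Precursor Biosynthesis	GANAB	SSAFR	4e-07	5.6e-06
CNX_CRT	EDEM3	OCE	1e-10	1.4e-09
CNX_CRT	GCS1	MENA	2e-14	2.8e-13
CNX_CRT	GCS1	EUR	2e-16	2.8e-15
CNX_CRT	GCS1	CSASIA	2e-06	2.8e-05
CNX_CRT	UGCGL2	SSAFR	4e-05	5.6e-04
Branching 1	FUT8	SSAFR	1e-04	1.4e-03
Branching 1	MAN1A1	AME	5e-13	7.0e-12
Branching 1	MAN1A2	SSAFR	8e-04	1.12e-02
Branching 1	MAN2A1	SSAFR	4e-23	5.6e-22
Branching 1	MAN2A1	EASIA	3e-10	4.2e-09
Branching 1	MGAT2	EASIA	4e-07	5.6e-06
Branching 1	MGAT3	EASIA	1e-14	1.4e-13
Branching 2	MGAT5B	MENA	1e-07	1.4e-06
Branching 2	MGAT5B	EUR	7e-08	9.8e-07
Branching 2	ST8SIA3	MENA	5e-10	7.0e-09
Branching 2	ST8SIA3	EUR	2e-08	2.8e-07
Substrates	DPM1	MENA	5e-12	7.0e-11
Substrates	DPM1	EUR	1e-08	1.4e-07
Substrates	DPM1	CSASIA	2e-16	2.8e-15
Substrates	DOLPP1	CSASIA	2e-05	2.8e-04
Substrates	DPM2	EUR	5e-07	7.0e-06
Substrates	DPM3	EASIA	6e-30	8.4e-29
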