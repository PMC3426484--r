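sub_pathway	gene	continental_group	p_value	corrected_p
Branching 1	MAN2A2	CSASIA	3e-12	4.2e-11
Branching 1	MGAT3	CSASIA	2e-08	2.8e-07
Branching 2	B4GALT2	MENA	2e-07	2.8e-06
Branching 2	MGAT4A	EUR	3e-06	4.2e-05
Branching 2	MGAT4A	EASIA	3e-06	4.2e-05
Branching 2	ST3GAL4	SSAFR	3e-07	4.2e-06
Branching 2	ST8SIA3	EUR	2e-07	2.8e-06
Branching 2	ST8SIA6	CSASIA	3e-06	4.2e-05
Substrates	DPM1	MENA	3e-08	4.2e-07
Substrates	DPM3	CSASIA	2e-24	2.8e-23
Substrates	PMM1	EASIA	8e-07	1.1e-05
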