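protein_id	peptide_id	start	end	peptide_sequence
g1	planted_1	10	12	IPP
g1	planted_2	40	42	VPP
g2	planted_3	25	27	IPI
g2	planted_4	60	61	WV
g3	planted_5	5	7	LHH
g4	planted_6	30	34	YGGFL
g5	planted_7	50	51	IY
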