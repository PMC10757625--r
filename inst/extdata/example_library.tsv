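biopeptide_ID	biopeptid_name	peptide_sequence	chemical_mass	biological_activity_category
EX001	antihypertensive lactotripeptide	IPP	325.41	ACE inhibitor
EX002	antihypertensive lactotripeptide	VPP	311.38	ACE inhibitor
EX003	ACE inhibitor from fish muscle	LKP	356.47	ACE inhibitor
EX004	ACE inhibitor dipeptide	IY	294.35	ACE inhibitor;antioxidative
EX005	ACE inhibitor dipeptide	VY	280.32	ACE inhibitor
EX006	diprotin A	IPI	341.45	DPP-4 inhibitor
EX007	diprotin B	VPL	327.42	DPP-4 inhibitor
EX008	DPP-4 inhibitor dipeptide	WV	303.36	DPP-4 inhibitor
EX009	antioxidative peptide	LHH	405.46	antioxidative
EX010	opioid fragment	YGGFL	555.63	opioid
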