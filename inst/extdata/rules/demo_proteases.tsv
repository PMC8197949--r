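protease_id	catalytic_class	human	P4	P3	P2	P1	P1p	P2p	P3p	P4p
TRYP_LIKE	serine	TRUE	*	*	*	KR	*	*	*	*
CHYM_LIKE	serine	TRUE	*	*	*	FWY	*	*	*	*
ELAS_LIKE	serine	TRUE	*	*	*	AVG	*	*	*	*
CASP_LIKE	cysteine	TRUE	*	*	*	D	G	*	*	*
MMP_LIKE	metallo	TRUE	P	*	G	*	LI	*	*	*
PEPS_LIKE	aspartic	TRUE	*	*	*	FL	FLWY	*	*	*
GLUC_LIKE	serine	TRUE	*	*	*	E	*	*	*	*
NONHUMAN_DEMO	serine	FALSE	*	*	*	KR	*	*	*	*
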