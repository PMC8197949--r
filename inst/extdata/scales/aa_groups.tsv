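group	residues
acidic	DE
aromatic	FHWY
basic	HKR
charged	DEHKR
hydrophobic	ACFGILMPVWY
polar_charged	DEHKR
polar_non_charged	CNQSTY
small	ACDGNPSTV
tiny	ACGST
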