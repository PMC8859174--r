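v.segm	j.segm	cdr3	antigen.epitope	antigen.species	mhc.a
TRBV2	TRBJ1-1	CASSTSENTEAF	GLCTLVAML	EBV	A*02:01
TRBV9	TRBJ2-2	CASSGGASGELF	RAKFKQLL	EBV	B*08:01
TRBV9	TRBJ1-2	CASSVEGPGYTF	YVLDHLIVV	EBV	A*02:01
TRBV2	TRBJ2-3	CASSLGTGTQYF	FLRGRAYGL	EBV	B*08:01
TRBV2	TRBJ2-3	CASSLTTQGVDTQYF	NLVPMVATV	CMV	A*02:01
TRBV5	TRBJ1-1	CASSWRRGPEAF	TPRVTGGGAM	CMV	B*07:02
TRBV5	TRBJ2-5	CASSLGQGRETQYF	VTEHDTLLY	CMV	A*01:01
TRBV12	TRBJ2-1	CASSLRDRGRDEQFF	IPSINVHHY	CMV	B*35:01
TRBV7	TRBJ2-3	CASSDRGPDTQYF	GILGFVFTL	InfluenzaA	A*02:01
TRBV2	TRBJ2-3	CASSLLDTQYF	PKYVKQNTLKLAT	InfluenzaA	DRB1*15:01
TRBV9	TRBJ2-2	CASSVTGSGELF	CTELKLSDY	InfluenzaA	A*01:01
TRBV28	TRBJ2-1	CASSLQQGGNEQFF	SRYWAIRTR	InfluenzaA	B*27:05
TRBV19	TRBJ1-5	CASSRTSEPQHF	VHFFKNIVTPR	HomoSapiens	DRB1*15:01
TRBV28	TRBJ1-5	CASSLSQGQPQHF	PLPSQGSLYT	HomoSapiens	DRB1*15:01
TRBV7	TRBJ1-2	CASSGTGEGYTF	ENPVVHFFKNIVTP	HomoSapiens	DRB1*15:01
TRBV5	TRBJ2-3	CASSSLDTQYF	KTTTSILDI	HomoSapiens	A*68:01
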