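name	pattern	smiles	ion
ammonium	N:1,H:4,Q:1	[NH4+]	TRUE
ammonia	N:1,H:3	N	FALSE
water	O:1,H:2	O	FALSE
hydroxide	O:1,H:1,Q:-1	[OH-]	TRUE
hydrogen	H:2	[H][H]	FALSE
dioxygen	O:2	O=O	FALSE
difluorine	F:2	FF	FALSE
dichlorine	Cl:2	ClCl	FALSE
dibromine	Br:2	BrBr	FALSE
diiodine	I:2	II	FALSE
proton	H:1,Q:1	[H+]	TRUE
oxygen	O:1	[O]	FALSE
fluoride	F:1,Q:-1	[F-]	TRUE
chloride	Cl:1,Q:-1	[Cl-]	TRUE
bromide	Br:1,Q:-1	[Br-]	TRUE
iodide	I:1,Q:-1	[I-]	TRUE
sodium	Na:1,Q:1	[Na+]	TRUE
potassium	K:1,Q:1	[K+]	TRUE
magnesium	Mg:1,Q:2	[Mg+2]	TRUE
electron	Q:-1	[e-]	TRUE
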