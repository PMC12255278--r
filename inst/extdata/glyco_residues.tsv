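name	composition	aliases
hexose	C6H10O5	Hex;hex
deoxyhexose	C6H10O4	dHex;DeOxHex;dhex
pentose	C5H8O4	Pen;pen
malonylhexoside	C9H12O8	MalHex;malhex;Mal
hydroxylation	O1	O
saturation	H2	H2
acetylation	C2H2O1	Ac;acetyl
water	H2O1	H2O
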