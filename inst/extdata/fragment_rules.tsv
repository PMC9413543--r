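type	mz	class	note
fragment	184.0733	phosphocholine head group (LPC/PC)	protonated phosphocholine C5H15NO4P
fragment	85.0268	acylcarnitine	acylcarnitine diagnostic fragment
neutral_loss	141.0191	LPE (phosphoethanolamine loss)	loss of phosphoethanolamine
neutral_loss	60.0211	formate-adduct LPC (methyl formate loss)	loss of methyl formate from [M+COOH]-
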