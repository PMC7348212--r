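name	sequence	orientation
Eub338	ACTCCTACGGGAGGCAGCAG	forward
Eub518	ATTACCGCGGCTGCTGG	reverse
DSBB280F	CGATGGTTAGCGGGTCTG	forward
DSBB280wF	CGATGGTTARCGGGTCTG	forward
SRB385R	CGGCGTCGCTGCGTCAGG	reverse
ELF645F	CTTGGCTTGAGTATCAGAGG	forward
ELF645wF	CYTGGCTTGAGTATCAGAGG	forward
CB836R	CCTGCACCTAGTTGACATCG	reverse
CB836wR	CCTGCAYCTAGTTGACATCG	reverse
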