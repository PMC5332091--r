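name	pattern	class
ABRE	ACGTGKC	ABA
MBS	CAACTG	drought
HSE	AGAANWTTC	heat
LTR	CCGAAA	low_temperature
TC-rich_repeats	ATTTTCTTCA	defense_stress
TGA-element	AACGAC	auxin
ERE	ATTTCAAA	ethylene
P-box	CCTTTTG	gibberellin
GARE-motif	TCTGTTG	gibberellin
CGTCA-motif	CGTCA	MeJA
TGACG-motif	TGACG	MeJA
TCA-element	CCATCTTTTT	salicylic_acid
ARE	AAACCA	anaerobic
circadian	CAANNNNATC	circadian
WUN-motif	AAATTACT	wound
Sp1	GGGCGG	light
G-box	CACGTG	light
GATA-motif	GATAGGR	light
Box4	ATTAAT	light
CAT-box	GCCACT	meristem
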