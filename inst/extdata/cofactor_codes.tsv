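comp_id	label
ZN	zinc ion
MG	magnesium ion
MN	manganese ion
FE	iron ion
FE2	iron (II) ion
CU	copper ion
CA	calcium ion
NA	sodium ion
K	potassium ion
NI	nickel ion
CO	cobalt ion
MO	molybdenum ion
HEM	protoporphyrin IX + Fe
HEC	heme C
NAD	nicotinamide adenine dinucleotide
NAP	NADP
FAD	flavin adenine dinucleotide
FMN	flavin mononucleotide
PLP	pyridoxal 5'-phosphate
SAM	S-adenosylmethionine
COA	coenzyme A
TPP	thiamine diphosphate
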