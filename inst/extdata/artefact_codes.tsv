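comp_id	label
HOH	water
GOL	glycerol
EDO	ethylene glycol
PEG	polyethylene glycol
MPD	2-methyl-2,4-pentanediol
ACT	acetate
SO4	sulfate
PO4	phosphate
NO3	nitrate
FMT	formate
CIT	citrate
TRS	tris buffer
EPE	HEPES buffer
MES	MES buffer
BCN	bicine buffer
DMS	dimethyl sulfoxide
CL	chloride ion
BR	bromide ion
EOH	ethanol
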