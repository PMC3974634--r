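cassette_id	NEO
arm_length_left	1000
arm_length_right	1000
id	arm	distance	kind
NdeI	LEFT	950	SNP
EcoRI	LEFT	800	SNP
LHP	LEFT	650	HAIRPIN
NcoI	LEFT	547	SNP
AseI	LEFT	300	SNP
SspI	RIGHT	130	SNP
SacI	RIGHT	261	SNP
RHP	RIGHT	400	HAIRPIN
XbaI	RIGHT	600	SNP
SbfI	RIGHT	800	SNP
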