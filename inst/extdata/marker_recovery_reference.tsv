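marker	compartment	cell_type	fraction	percent	sem
visual pigment	OS_membrane	rod	upper	86.2	13.4
visual pigment	OS_membrane	rod	lower	0.9	0.2
F1 ATPase beta subunit	mito_inner	rod	upper	ND	NA
F1 ATPase beta subunit	mito_inner	rod	lower	84.8	4.3
TOM20	mito_outer	rod	upper	9.1	0.4
TOM20	mito_outer	rod	lower	42.5	7.0
Na+/K+ ATPase alpha subunit	IS_plasma	rod	upper	65.7	9.5
Na+/K+ ATPase alpha subunit	IS_plasma	rod	lower	40.2	1.2
calnexin	ER	rod	upper	26.5	4.3
calnexin	ER	rod	lower	9.9	3.1
visual pigment	OS_membrane	cone	upper	54.5	3.2
visual pigment	OS_membrane	cone	lower	3.5	0.2
F1 ATPase beta subunit	mito_inner	cone	upper	3.5	0.9
F1 ATPase beta subunit	mito_inner	cone	lower	54.6	4.4
TOM20	mito_outer	cone	upper	6.86	1.5
TOM20	mito_outer	cone	lower	58.2	12.3
Na+/K+ ATPase alpha subunit	IS_plasma	cone	upper	49.0	8.0
Na+/K+ ATPase alpha subunit	IS_plasma	cone	lower	10.9	1.6
calnexin	ER	cone	upper	35.5	3.1
calnexin	ER	cone	lower	38.4	5.3
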