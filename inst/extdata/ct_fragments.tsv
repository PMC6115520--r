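# TBDMS-derivatized proteinogenic amino acid fragments measured by GC-MS.
# carbon_set: 1-based skeleton carbon positions retained by the ion
# (C1 = carboxyl). M-57 ions retain the full skeleton; M-85 ions lack C1;
# the f302-type glutamate ion covers C1-C2 ("Glu1-2"); Glu_M85 covers
# C2-C5 ("Glu2-5").
# formula: nominal elemental composition of the ion excluding skeleton
# carbons (skeleton carbons carry the biological label and are excluded
# from natural-abundance correction by convention).
fragment	amino_acid	carbon_set	formula
Ala_M57	ALA	1-3	C8H26NO2Si2
Ala_M85	ALA	2-3	C8H26NOSi2
Gly_M57	GLY	1-2	C8H24NO2Si2
Ser_M57	SER	1-3	C14H40NO3Si3
Ser_M85	SER	2-3	C14H40NO2Si3
Asp_M57	ASP	1-4	C14H40NO4Si3
Asp_M85	ASP	2-4	C14H40NO3Si3
Thr_M57	THR	1-4	C14H42NO3Si3
Glu_M57	GLU	1-5	C14H42NO4Si3
Glu_M85	GLU	2-5	C14H42NO3Si3
Glu_f302	GLU	1-2	C10H26NO2Si2
Ile_M57	ILE	1-6	C8H32NO2Si2
Ile_M85	ILE	2-6	C8H32NOSi2
Val_M57	VAL	1-5	C8H30NO2Si2
Val_M85	VAL	2-5	C8H30NOSi2
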