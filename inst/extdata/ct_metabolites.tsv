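# Metabolites of the C. thermocellum central carbon model.
# role: balanced (mass-balanced at steady state), source (fed substrate,
# labelable), sink (excreted product / biomass, never balanced).
id	n_carbons	role
GLCX	6	source
CO2X	1	source
FORX	1	source
G6P	6	balanced
F6P	6	balanced
FBP	6	balanced
DHAP	3	balanced
GAP	3	balanced
PGA	3	balanced
PEP	3	balanced
PYR	3	balanced
ACCOA	2	balanced
OAA	4	balanced
MAL	4	balanced
CIT	6	balanced
ICT	6	balanced
OG	5	balanced
RU5P	5	balanced
X5P	5	balanced
R5P	5	balanced
S7P	7	balanced
E4P	4	balanced
CO2	1	balanced
FOR	1	balanced
METHF	1	balanced
GLY	2	balanced
SER	3	balanced
ALA	3	balanced
ASP	4	balanced
GLU	5	balanced
THR	4	balanced
ILE	6	balanced
VAL	5	balanced
OBUT	4	balanced
LACX	3	sink
ACEX	2	sink
ETOHX	2	sink
FORSNK	1	sink
CO2SNK	1	sink
BIOM	0	sink
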