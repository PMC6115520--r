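# Atom-mapped central carbon network of C. thermocellum DSM 1313.
# Reconstructed from genome-validated pathway knowledge: EMP glycolysis,
# nonoxidative pentose phosphate pathway, malate shunt, incomplete TCA cycle
# initiated by both Si- and Re-citrate synthase (no oxidative route from
# 2-oxoglutarate to oxaloacetate, no fumarase), pyruvate ferredoxin
# oxidoreductase (reversible, the route by which medium bicarbonate labels
# pyruvate C1), pyruvate formate lyase, one-carbon (formate/folate)
# metabolism with reversible serine hydroxymethyltransferase and glycine
# cleavage, citramalate and threonine routes to isoleucine, and fermentation
# to lactate, acetate, ethanol, formate and CO2.
#
# Atom maps: lowercase letters, one per carbon, local to each reaction.
# Carbon positions are 1-based; for amino acids C1 is the carboxyl carbon.
# CO2/bicarbonate is one well-mixed pool with a labelable medium source
# (CO2X) and an excretion sink.
#
# The biomass equation (no atom maps: a pure drain) uses placeholder
# coefficients in the style of a generic bacterial biomass composition;
# it is a synthetic stand-in, not a published measurement.

# glucose uptake and EMP glycolysis
GLCUP: GLCX (abcdef) -> G6P (abcdef)
PGI: G6P (abcdef) <-> F6P (abcdef)
PFK: F6P (abcdef) -> FBP (abcdef)
FBA: FBP (abcdef) <-> DHAP (abc) + GAP (def)
TPI: DHAP (abc) <-> GAP (cba)
GAPD: GAP (abc) <-> PGA (abc)
ENO: PGA (abc) <-> PEP (abc)
PK: PEP (abc) -> PYR (abc)
PPDK: PEP (abc) <-> PYR (abc)

# anaplerosis and malate shunt
PEPC: PEP (abc) + CO2 (d) -> OAA (abcd)
MDH: OAA (abcd) <-> MAL (abcd)
ME: MAL (abcd) -> PYR (abc) + CO2 (d)

# pyruvate node and fermentation
PFOR: PYR (abc) <-> ACCOA (bc) + CO2 (a)
PFL: PYR (abc) -> ACCOA (bc) + FOR (a)
LDH: PYR (abc) -> LACX (abc)
PTA: ACCOA (ab) -> ACEX (ab)
ADH: ACCOA (ab) -> ETOHX (ab)

# incomplete TCA cycle; two stereospecific citrate synthases.
# Si-CS: acetyl carbons end at glutamate C4-C5 (C5 = acetate carboxyl);
# Re-CS: the two citrate arms swap, acetyl carbons end at glutamate C1-C2.
CS_SI: OAA (abcd) + ACCOA (ef) -> CIT (dcbfea)
CS_RE: OAA (abcd) + ACCOA (ef) -> CIT (efbcda)
ACO: CIT (abcdef) <-> ICT (abcdef)
ICTDH: ICT (abcdef) -> OG (abcde) + CO2 (f)
GLUS: OG (abcde) -> GLU (abcde)

# nonoxidative pentose phosphate pathway
RPE: RU5P (abcde) <-> X5P (abcde)
RPI: RU5P (abcde) <-> R5P (abcde)
TKT1: X5P (abcde) + R5P (fghij) <-> GAP (cde) + S7P (abfghij)
TAL: S7P (abcdefg) + GAP (hij) <-> E4P (defg) + F6P (abchij)
TKT2: X5P (abcde) + E4P (fghi) <-> GAP (cde) + F6P (abfghi)

# one-carbon metabolism
FORIN: FORX (a) -> FOR (a)
MTHF: FOR (a) -> METHF (a)
GCV: CO2 (a) + METHF (b) <-> GLY (ab)
SHMT: GLY (ab) + METHF (c) <-> SER (abc)
FOROUT: FOR (a) -> FORSNK (a)

# CO2 pool exchange with the medium (bicarbonate)
CO2IN: CO2X (a) -> CO2 (a)
CO2OUT: CO2 (a) -> CO2SNK (a)

# amino acid biosynthesis
SERS: PGA (abc) -> SER (abc)
ALAS: PYR (abc) -> ALA (abc)
ASPS: OAA (abcd) -> ASP (abcd)
THRS: ASP (abcd) -> THR (abcd)
# isoleucine: citramalate route (keeps pyruvate C1 as the isoleucine
# carboxyl, releases the acetate carboxyl as CO2) vs threonine deaminase
CIMS: PYR (abc) + ACCOA (de) -> OBUT (abce) + CO2 (d)
THRDA: THR (abcd) -> OBUT (abcd)
ILES: OBUT (abcd) + PYR (efg) -> ILE (abfcdg) + CO2 (e)
VALS: PYR (abc) + PYR (def) -> VAL (abecf) + CO2 (d)

# biomass drain (placeholder generic composition; synthetic stand-in)
BIOMASS: 0.20 G6P + 0.50 R5P + 0.30 E4P + 0.10 PGA + 0.05 PEP + 0.30 PYR + 0.25 ACCOA + 0.15 OAA + 0.05 OG + 0.80 SER + 0.80 GLY + 0.10 ALA + 0.06 ASP + 0.06 GLU + 0.50 THR + 0.40 ILE + 0.60 VAL + 0.20 METHF -> BIOM
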