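# Default ground-truth net-flux regime for the packaged reference network,
# on the glucose-uptake = 100 scale: dominant EMP glycolysis directed to
# fermentation products, active malate shunt and one-carbon metabolism,
# PPDK-dominant PEP-to-pyruvate conversion, small oxidative TCA branch
# feeding glutamate, citramalate-dominant isoleucine synthesis, and
# nonoxidative pentose phosphate flux toward biomass pentoses. These are
# package defaults for synthetic experiments (projected exactly onto the
# steady-state manifold at load time), not published measurements.
reaction	net
GLCUP	100
PGI	98
PFK	93.667
FBA	93.667
TPI	93.667
GAPD	183.667
ENO	170.667
PK	21.567
PPDK	120
PEPC	28.6
MDH	20
ME	20
PFOR	92.967
PFL	30
LDH	15
PTA	65
ADH	50.767
CS_SI	0.55
CS_RE	0.55
ACO	1.1
ICTDH	1.1
GLUS	0.6
RPE	-4.333
RPI	4.333
TKT1	-0.667
TAL	-0.667
TKT2	-3.667
FORIN	0
MTHF	2
GCV	4
SHMT	-4
FOROUT	28
CO2IN	25
CO2OUT	120.067
SERS	12
ALAS	1
ASPS	6
THRS	5.4
CIMS	3.6
THRDA	0.4
ILES	4
VALS	6
BIOMASS	10
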