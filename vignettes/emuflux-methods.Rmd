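---
title: "Steady-state 13C flux analysis with emuflux: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state 13C flux analysis with emuflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

## The problem

In a steady-state ¹³C tracer experiment, cells grow on an isotopically
defined substrate mixture (for instance 20 % [U-¹³C₆] glucose and 80 %
unlabeled glucose, or ¹³C-bicarbonate alongside unlabeled glucose) until
both metabolic fluxes and isotope labeling are stationary. Proteinogenic
amino acids are hydrolyzed, derivatized (TBDMS) and measured by GC-MS as
fragment ions. The fractional abundances of the isotopologues of a
fragment form its mass isotopomer distribution vector (MDV), m₀…mₙ over
the n skeleton carbons, normalized to unit sum. Because each amino acid is
drawn from a specific central-metabolic precursor, the MDVs encode the
relative fluxes through the pathways that synthesize those precursors.

`emuflux` implements the full chain from raw fragment intensities to a
glucose-normalized flux map for the central carbon network of the
anaerobic cellulolytic bacterium *Clostridium thermocellum*:

1. **MS processing** — intensity normalization, natural-abundance
   correction, fractional labeling;
2. **forward simulation** — steady-state fragment MDVs from an
   atom-mapped network, a flux vector and a tracer, via elementary
   metabolite unit (EMU) decomposition, with an exhaustive isotopomer
   simulator as an independent oracle;
3. **local flux ratios** — closed-form constrained mixture fits at branch
   points (glycolytic route of serine, one-carbon contribution to serine,
   oxidative-TCA contribution to oxaloacetate, citrate-synthase
   stereochemistry, isoleucine biosynthetic route);
4. **global flux estimation** — weighted least squares over a free-flux
   parameterization with multi-start Levenberg–Marquardt, χ² goodness of
   fit and profile-likelihood confidence intervals.

## The network model

The packaged network (`ct_network()`) encodes EMP glycolysis, the
nonoxidative pentose phosphate pathway, the malate shunt
(PEP → OAA → malate → pyruvate), the PPDK/PK routes from PEP to pyruvate,
reversible pyruvate:ferredoxin oxidoreductase (PFOR), pyruvate formate
lyase, an **incomplete** TCA branch ending at 2-oxoglutarate, both *Si*-
and *Re*-citrate synthase, one-carbon (formate/folate) metabolism with
reversible serine hydroxymethyltransferase and glycine cleavage, and the
citramalate and threonine routes to isoleucine. The oxidative pentose
phosphate pathway, the ED pathway and fumarase are absent, matching the
organism's genome annotation and the labeling evidence. Cofactor
(NAD(P)H/ferredoxin) balancing is deliberately out of scope: which
cofactor a given oxidoreductase uses is not reliably annotated, and
imposing guesses would bias the carbon flux estimates.

Atom transitions are written as per-metabolite lowercase letter strings,
local to each reaction (`PFOR: PYR (abc) <-> ACCOA (bc) + CO2 (a)`),
1-based, with C1 the carboxyl carbon of amino acids. Two conventions
deserve comment:

* **Citrate synthase stereochemistry.** With the *Si* enzyme the acetyl
  carbons end at glutamate C4–C5 (C5 = acetate carboxyl) and the
  CO₂-derived OAA C4 appears at glutamate C1; with the *Re* enzyme the two
  citrate arms swap, so the OAA C4 label appears at glutamate C5 and the
  acetyl carbons at C1–C2. Under ¹³C-bicarbonate labeling the two enzymes
  therefore label the two glutamate GC-MS fragments (C1-C2 vs C2-C5)
  distinguishably.
* **Citramalate route.** The atom map retains pyruvate C1 as the
  2-oxobutyrate (and ultimately isoleucine) carboxyl and releases the
  acetate-derived carboxyl as CO₂, so that under bicarbonate labeling the
  route leaves a single label confined to isoleucine C1. Beyond C1/C2 the
  internal ordering of the lumped isoleucine map is nominal; only the
  C1-containing vs C1-lacking fragment contrast is interpreted.

CO₂/bicarbonate is one well-mixed pool with a labelable medium source and
an excretion sink; internally produced CO₂ re-enters it, which is how
reversed PFOR labels pyruvate C1 under bicarbonate tracing. Reversible
reactions are net + exchange (exchange ≥ 0), keeping the steady-state
constraint linear in net fluxes. Succinate/fumarate scrambling is not
modeled because fumarase is absent from the network. The biomass equation
drains precursors with placeholder coefficients in the style of a generic
bacterial composition; it is a synthetic stand-in and is labeled as such
in the fixture file.

## Simulation: EMU with an exhaustive oracle

Fragment MDVs are simulated by EMU decomposition: starting from each
measured fragment (a metabolite plus a carbon subset), precursor EMUs are
traced through every producing reaction; condensations become
convolutions of smaller EMUs. Unknowns of equal size satisfy one linear
balance per EMU — total production flux times the EMU's MDV equals the
flux-weighted sum of source MDVs — solved densely size by size. Zero-flux
reactions are dropped from the balances; an EMU with zero total
production raises a named error rather than propagating NaN. The packaged
network yields ~150 EMUs for the full fragment panel and solves in about
2 ms, which is what makes multi-start fitting and profile likelihoods
affordable.

`brute_force_simulate()` is the independent correctness oracle: it solves
the complete positional-isotopomer balance (2ⁿ states per metabolite, a
guard caps the total state space) by damped fixed-point iteration and
agrees with the EMU path to below 10⁻⁸ per mass on every packaged network,
including the full reference model.

Tracer inputs are idealized by default: "unlabeled" means zero ¹³C, so
analytic values (the 20 % enrichment check, the serine m₁ = 0.5
signature) come out exact. Setting `natural_13c = TRUE` gives unlabeled
positions the natural 1.07 % ¹³C abundance for realistic synthetic data.

## MS processing

The correction matrix maps the true skeleton MDV to the observed one: its
columns are the mass-shift distribution of the fragment's non-skeleton
atoms (convolution of per-element isotope distributions from a packaged,
versioned abundance table), shifted by the skeleton mass. Correction
inverts this linear map, truncates to the skeleton carbon count, clamps
negatives within 10⁻⁶ silently (larger deficits trigger a data-quality
warning) and renormalizes. By default only C, H and O are corrected,
a widespread convention for amino-acid GC-MS data; N/Si/S correction for
TBDMS derivatization groups is available through the `elements` argument.
The two conventions give measurably different corrections, so the choice
is an explicit, recorded parameter rather than a hidden default. The mass window
defaults to n + 4 shifts; truncation loss beyond 10⁻³ is flagged.
Fractional labeling is FL = Σᵢ i·mᵢ / n.

## Flux ratios

All branch-point estimators are constrained least squares on the
two-endmember mixture model observed = f·a + (1−f)·b with f ∈ [0, 1],
solved in closed form and clamped. Endmember MDVs are simulated under the
actual tracer rather than hard-coded, so tracer impurities propagate
consistently. The oxidative-OAA estimator builds its endmembers from
precursor EMUs: OAA-from-2OG maps 2-oxoglutarate C2–C5 onto OAA C1–C4;
OAA-from-anaplerosis convolves PEP C1–C3 with the CO₂ pool. Because a
metabolite's steady-state MDV is exactly the flux-weighted mixture of its
producers' MDVs, the estimator recovers a known oxidative fraction
exactly on networks where the route carries flux, and returns f = 0 on
the reference network, which has no 2OG → OAA path. The
citrate-synthase stereochemistry report classifies Re/Si activity from m₁
of the glutamate C2-C5 and C1-C2 fragments with a default evidence
threshold of 0.10 — chosen midway between noise level (< a few percent)
and the clearly positive signals (> 25 %) the classifier is meant to
detect; it is configurable.

## Global fitting

Net fluxes are parameterized on the null space of the stoichiometric
matrix (augmented with fixed-value constraints such as glucose uptake =
100), so every optimizer iterate balances exactly; irreversibility enters
as smooth penalty residuals, and exchange fluxes are optimized on the
bounded transform exch/(exch + c) with c = 10× glucose uptake. The
objective is the variance-weighted SSR over all MDV mass channels,
extracellular rates, and ratio pseudo-measurements. Two such
pseudo-measurements ship with the default synthetic dataset — the PPDK
share of PEP→pyruvate and the malate-shunt share of pyruvate formation —
because these routes form no distinguishable carbon-carbon bonds and are
structurally invisible to steady-state labeling; constraining them from
independent experiments is standard for this network.

The SSR landscape is non-convex: random feasible starts (hit-and-run
samples of the flux polytope) reach the global basin roughly 15–30 % of
the time, so the fitter defaults to 20 restarts; the examples and tests
use 5–8 restarts where the budget matters and the quantity checked is
robust to an occasional local minimum. Degrees of freedom count each
fragment's masses minus one (the unit-sum channel is redundant) plus
rates and ratio constraints, minus free parameters. Goodness of fit
compares the SSR to the central χ² interval at those degrees of freedom.

Confidence intervals are profile likelihoods: each flux is pinned (via a
tight pseudo-measurement), all other parameters re-optimized from warm
starts, and the crossing of SSR_min + χ²₁(0.95) located by outward
doubling plus bisection (default resolution 10⁻³ flux units; coverage
tests use 10⁻² to keep replicate counts high). Sides that never cross
before a search cap are reported open-ended and flagged — that is the
designed behavior for structurally unidentifiable directions, not a
failure.

## Synthetic data: what it emulates and what it does not

`simulate_dataset()` adds independent Gaussian noise (default sd 0.005
absolute mole fraction, consistent in magnitude with sub-1 % GC-MS
replicate errors) to each mass channel, clamps negatives and renormalizes
to unit sum, reporting the configured sd as the measurement sd.
Renormalization makes channels within a fragment weakly anticorrelated
and rescales the effective sd of a channel with abundance m in a
k-channel fragment by √(1 − 2m + k·m²) — up to ~±15 % at extreme
abundances. Consequences worth knowing:

* empirical channel sds match the configured value only after that
  analytic factor (the test suite checks exactly this);
* profile-likelihood coverage under MDV-channel noise runs a few percent
  below nominal (we measured ≈ 89–90 % for a nominal 95 % on a
  one-parameter toy), because the fit assumes independent errors. The
  coverage calibration test therefore uses an independent-Gaussian rate
  measurement, the setting where the χ² threshold is exact.

Real GC-MS data add effects the generator does not emulate:
chromatographic integration error, detector nonlinearity, imperfect
derivatization, amino-acid dilution from rich-medium nutrients, and
deviations from isotopic steady state. Passing the synthetic recovery
suite therefore demonstrates correctness of the estimator chain under the
stated error model, not robustness to all laboratory artifacts.

The packaged ground-truth regime (`ct_reference_fluxes()`) fixes the
study conditions for synthetic experiments: glucose uptake 100
(normalized), dominant glycolysis feeding lactate/formate/acetate/
ethanol, active malate shunt (~20 % of pyruvate formation via PPDK+PK+ME),
PPDK-dominant PEP conversion, a small oxidative TCA branch sized by the
glutamate demand of biomass, citramalate-dominant isoleucine synthesis
(90 %), and an active one-carbon pathway. The target table is projected
exactly onto the steady-state manifold at load time; the values are
package defaults, documented in the fixture, and are not claimed to be
published measurements.

## Numerical choices

* Linear systems: dense LU (`solve`) per EMU size level; singularity
  surfaces as a named error. Flux terms below 10⁻¹² × max flux are
  dropped from balances.
* Free-flux basis: SVD with rank tolerance 10⁻⁹ × largest singular
  value; infeasible fixed values report the violated balance rows.
* Brute-force oracle: Gauss–Seidel iteration to 10⁻¹³ max change,
  state-space guard 2²⁰ summed states.
* Optimizer: `minpack.lm::nls.lm`, ftol 10⁻¹², ptol 10⁻¹⁰, generous
  function-evaluation budget; restarts drawn by seeded hit-and-run. All
  randomness flows from explicit seeds and the caller's RNG state is
  restored, so identical seeds give bit-identical results.
* Problem sizes used by the shipped tests: the reference network (43
  reactions, 31 balanced metabolites, 11 free parameters), 20 noisy
  replicate fits at sd 0.005, 25-seed oracle-equivalence sweeps on the
  toy fixtures, and 200-replicate coverage runs on a one-parameter toy.

## Known limitations

* Steady-state only: no isotopically nonstationary (kinetic) simulation.
* The biomass composition and parts of the lumped amino-acid atom maps
  are nominal stand-ins where no authoritative values were available;
  they are marked as such in the fixture files.
* Measurement weighting treats the reported per-mass sd as independent
  Gaussian; correlated channel noise (from unit-sum normalization) is not
  modeled in the objective.
* Parallel routes without distinguishing atom rearrangements (PK vs
  PPDK, malate shunt magnitude) are unidentifiable from labeling alone
  by design of the chemistry; they require ratio pseudo-measurements,
  and their profile intervals are open when those are absent.
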