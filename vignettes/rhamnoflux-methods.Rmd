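---
title: "Models and methods behind rhamnoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhamnoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhamnoflux)
```

`rhamnoflux` analyses mono-rhamnolipid production from ethanol by
engineered *Pseudomonas putida*. This vignette documents the models the
package implements, the conventions and parameters it fixes, the design
choices that were genuinely open, and the limits of what its tests
demonstrate.

## 1. The core stoichiometric model

### Scope and bookkeeping

`build_core_model()` constructs a ~50-reaction network around ethanol
assimilation: ethanol enters either through the periplasmic quinoprotein
ethanol dehydrogenase (PedH, electrons to PQQ) or through a cytoplasmic
NAD⁺-dependent alcohol dehydrogenase (Adh); acetaldehyde is oxidised to
acetate (AldB, NAD⁺) and activated to acetyl-CoA (AcsA, at a cost of two
ATP equivalents once AMP recycling and diphosphate hydrolysis are
counted). Acetyl-CoA feeds the TCA cycle, the glyoxylate shunt (the only
anaplerotic entry from C2 units), gluconeogenesis to glucose 6-phosphate,
a lumped dTDP-L-rhamnose branch and a lumped fatty-acid-synthesis branch
to (R)-3-hydroxydecanoyl-ACP. An Entner–Doudoroff lump supports growth on
glucose for comparison.

All species carry their **neutral (fully protonated) formulas** and zero
formal charge. This makes every internal reaction exactly balanceable for
C, H, N, O, P and S by integer/simple-fraction coefficients, which
`check_balances()` verifies directly; translocated protons appear as
explicit `h_c`/`h_p` species and balance as hydrogen. The cost of this
convention is that proton stoichiometries of individual enzymes are not
literal physiological charges — acceptable here because only element and
energy accounting drive the results.

### Energy parameters

The respiratory chain distinguishes where electrons enter:

* NADH dehydrogenase pumps 4 H⁺ per electron pair, the terminal quinol
  oxidase 6 H⁺, so NADH electrons translocate 10 H⁺ on their way to O₂.
* PQQH₂ donates at the quinone level and sees only the oxidase: 6 H⁺.
* The ATP synthase consumes 4 H⁺ per ATP, giving effective P/O ratios of
  2.5 (NADH) and 1.5 (PQQH₂).

These proton numbers are arguments of `build_core_model()`, because the
biology fixes only their ordering (PQQ electrons must yield less usable
energy than NADH electrons), not their magnitudes. Growth-associated
maintenance is 50 mmol ATP per g biomass and growth-independent
maintenance 0.92 mmol g⁻¹ h⁻¹ — both in the range genome-scale
*P. putida* reconstructions use. The biomass equation drains G6P, PEP,
pyruvate, oxaloacetate, acetyl-CoA (40.6 mmol C per g CDW in total,
24.6 g per Cmol), NH₃, 12 mmol NADPH and the GAM ATP; it is a pseudo
reaction, exempt from elemental balancing but carbon-consistent, so FBA
solutions close their carbon balance to the solver tolerance.

One consequence worth stating plainly: with every carbon uptake closed
the default model is *infeasible*, not zero-growth, because nothing can
pay the maintenance bill. `build_core_model(ngam = 0)` gives the
maintenance-free form in which closed uptakes yield exactly zero growth.

### The rhamnolipid patch and cofactor scenarios

`extend_with_rhamnolipid_pathway()` adds RhlA
(2 β-hydroxydecanoyl-ACP + H₂O → HAA + 2 ACP, the water hydrolysing the
second thioester), RhlB (HAA + dTDP-L-rhamnose → Rha-C10-C10 + dTDP), and
export/exchange reactions, with HAA = C₂₀H₃₈O₅ and mono-rhamnolipid =
C₂₆H₄₈O₉. Precursor ids are remappable so the same patch applies to an
SBML genome-scale import. `apply_scenario()` closes the non-selected
ethanol-oxidation route (bounds (0,0)), leaving exactly one route with
capacity — the PQQ scenario mimics the wild type, the NAD scenario the
evolved strain in which quinoprotein oxidation is down-regulated.

### What the core model does and does not reproduce

Product-side optima at ethanol uptake 10 mmol g⁻¹ h⁻¹ emerge from the
stoichiometry: the carbon ceiling for Rha-C10-C10 on ethanol is
26/28 ≈ 0.93 Cmol Cmol⁻¹ (one CO₂ per PEP made for the rhamnose moiety),
and the energy balance pulls the PQQ scenario measurably below the NAD
scenario (optimal product fluxes ≈ 0.65 vs 0.71 mmol g⁻¹ h⁻¹; zero-growth
carbon yield ≈ 0.92 on ethanol vs ≈ 0.72 on glucose, a ~27% advantage).
At the *biomass* optimum, however, the lumped network is carbon-limited
under both scenarios (42.8 mmol biomass per mol ethanol either way): the
total electron flow — hence O₂ and CO₂ — is fixed by the
degree-of-reduction balance once the carbon allocation coincides, so the
scenario-dependent respiration signature that a genome-scale model
produces (through NADPH-coupled TCA demand and pathway-level detail) is
structurally outside a lumped model's reach. The acceptance suite keeps
those expectations at face value and lets them fail rather than relaxing
them.

## 2. The FBA engine

`fba()` maximises a reaction flux over \(\{v : Sv = 0,\ lb \le v \le
ub\}\). Rows of \(S\) made dependent by conserved moieties (cofactor
pools) are removed by QR factorisation before solving. The LP is solved
by a bounded-variable two-phase revised simplex implemented in the
package (`R/simplex.R`): FBA systems are heavily degenerate, and the
solver refactorises the basis at every iteration and switches to Bland's
rule after a run of degenerate steps, trading speed (irrelevant at these
sizes) for robustness. Its optima are cross-checked in the test suite
against brute-force vertex enumeration on hundreds of random toy networks
(agreement to 1e-9) and against an independent constraint-based toolchain
reading the same SBML file.

Alternate optima are resolved by a parsimonious secondary LP: total
absolute flux is minimised at the fixed optimal objective (split-variable
formulation). The objective value is the contract; reported flux vectors
are the parsimonious representative. Feasibility tolerance is 1e-9;
reported-value comparisons use 1e-6.

Yield conventions:

* `biomass_yield()` returns growth flux (h⁻¹) ÷ uptake × 1000, i.e.
  biomass counted as 1 g per mmol — the only basis on which
  "mmol biomass per mol ethanol" is dimensionally recoverable — and also
  carries the raw growth flux, since the published unit basis is
  inferred.
* `product_yield()` returns the proper molar ratio (product flux ÷
  uptake). One Rha-C10-C10 consumes 13–14 ethanol, so "0.63/0.71
  mmol mmol⁻¹"-style numbers cannot be molar ratios; they equal the
  optimal product *flux* at uptake 10, which the report exposes as
  `product_flux`.
* `product_yield_zero_growth()` fixes growth to (0,0), keeps
  maintenance, and converts to Cmol/Cmol with the species formulas.

## 3. SBML I/O

`read_sbml()`/`write_sbml()` handle the SBML Level 3 + FBC v2 subset that
constraint-based models actually use: species with chemical formula and
charge, reactions with parameter-referenced flux bounds, and the active
objective. Gene–protein associations, annotations and units are ignored.
Boundary-condition species are dropped so exchanges become single-species
reactions. Written files round-trip through the reader bit-faithfully in
stoichiometry, bounds and objective, and are readable by independent SBML
parsers.

## 4. The fed-batch simulator

### Process model

The simulated process is a 1 L (1.3 L nominal) stirred tank: a batch
phase on 7.6 g L⁻¹ ethanol (0.33 Cmol L⁻¹, inoculated at OD 0.5), foam
continuously exported to a collection bottle and pumped back, and a feed
phase in which a control script sprays 3 mL pure-ethanol pulses into the
foam bottle — collapsing the foam and feeding the reactor — whenever DO
rises to 40%, with a 5-minute pause after each trigger. The published
description alternates between that pause and a DO < 30% check as the OFF
mechanism; the simulator implements the lockout as primary and offers the
30% check as a config-selectable guard (`use_do_off_guard`).

States are masses (g) and volumes (L), so reactor↔bottle transfers
conserve mass identically. Kinetics: Monod growth on ethanol with
substrate inhibition and oxygen limitation
(μ = μ_max · S/(K_S+S) · K_i/(K_i+S) · DO/(K_DO+DO)); Luedeking–Piret
product formation (growth-associated α, non-growth-associated β); acetate
overflow as a fixed fraction of ethanol uptake with saturable
re-consumption; foam export proportional to gas flow and saturating in
product concentration; a return pump of fixed capacity. Cumulative CO₂
carbon is integrated as the exact negative sum of all other carbon
derivatives, making the closed carbon balance a linear invariant that the
fixed-step RK4 integrator (deSolve, substep 0.001 h inside a 1-minute
control loop) preserves to machine precision — the suite checks closure
below 1e-6 and observes ~1e-15.

### Dissolved oxygen

DO is *quasi-steady*: its relaxation time (1/kLa, seconds to ~2 min) is
far below the control-loop and substrate time scales, and integrating it
as a stiff ODE state inside fixed-step RK4 is unstable at high cell
density. `do_quasi_steady()` solves the transfer/uptake balance
kLa·(DO* − DO) = D·DO/(K_DO + DO) in closed form (positive quadratic
root), with DO* = 100·(O₂ fraction)/0.21. Agitation (to 1200 rpm, kLa ∝
rpm², 0.1 vvm) and then O₂ enrichment (to 90%) are raised one step per
control minute whenever DO sits below the 30% floor — mimicking the
cascade plus the operator's manual oxygen admixture. DO may therefore
read above 100% air saturation under enrichment, as a real air-calibrated
electrode would.

### Calibration

The published process reports setpoints and outcomes, not kinetic
constants, so `kinetic_params()` defaults are a calibration: μ_max 0.40
h⁻¹ (batch-phase realised rate ≈ 0.34 h⁻¹), Y_XS 0.45, Y_PS 0.25, α 0.20,
β 0.004, acetate overflow fraction 0.15 with uptake capacity 0.03 g g⁻¹
h⁻¹, q_O₂ 30 mmol g⁻¹, kLa 120 h⁻¹ at 1000 rpm and 0.1 vvm, ethanol
density 0.789 g mL⁻¹ (20 °C; a physical constant, used to convert fed
volume to mass). Under the defaults a 23 h run ends near 22 g L⁻¹ CDW and
4.5 g L⁻¹ biosurfactant after ~34 pulses (~0.1 L total feed), with a
feed-phase growth rate near 0.12 h⁻¹ and acetate accumulating late to
~8 g L⁻¹ — the intended regime (tens of pulses, order 90 mL, feed-phase
growth around 0.14 h⁻¹), reproduced as a calibration demonstration, not a
blind prediction.

## 5. Fermentation analytics

* Logistic fits use y(t) = y_min + (y_max − y_min)/(1 + e^{−k(t−t_m)}),
  one specific and documented member of the family of monotone
  four-parameter sigmoids; starts come from the data range and half-range
  crossing, optimisation is Levenberg–Marquardt (minpack.lm) within box
  constraints one span beyond the data, and estimates at a box edge or
  with a midpoint outside the observed time range raise a `boundary`
  flag (strictly linear input triggers it) rather than being reported as
  clean fits.
* `growth_rate()` is the least-squares slope of ln(OD) over a chosen or
  automatically selected maximum-slope window (≥3 points).
* Yields: space-time yield = titer/duration; Cmol yields use the C10-C10
  congener constants (HAA 358.5 g mol⁻¹/20 C, mono-rhamnolipid
  504.7 g mol⁻¹/26 C, ethanol 23.03 and glucose 30.03 g Cmol⁻¹);
  alternative congener tables can be supplied by recomputing with other
  masses. The acetate correction substitutes accumulated acetate by its
  Cmol-equivalent ethanol (g_ace × 2/59.04 × 23.03) in the denominator —
  a carbon argument, not an energy-weighted one. Whether the overall g/g
  yield should count the 6 mL manual prime in the fed volume is genuinely
  ambiguous, so `fermentation_yields()` reports both variants.

## 6. qPCR

Primer efficiency comes from the slope of Ct against log₂ concentration
over a ≥4-point (by design seven-point) two-fold dilution series:
E = 2^(−1/m), so perfect doubling (m = −1) gives E = 2. The log₂
convention is chosen because the dilution series is two-fold; the
attribute `slope_log10` carries the ten-fold-convention conversion
(m₁₀ = m·log₂10). Relative expression is plain 2^ΔCt against *rpoB*
(no efficiency-corrected ratios): technical replicates are averaged
before ΔCt, biological replicates are summarised by min/max, matching
the error-bar convention of the underlying measurements.

## 7. Synthetic data and what the tests show

Generators are bit-deterministic under their seed and return their
ground truth. Noise is multiplicative Gaussian (CV 2% by default) for
concentrations and additive (σ = 0.1 cycles) for Ct values, matching the
instruments' error structure; standard-curve points are technical-
triplicate means, as plates are read. The recovery suites (growth rate
and logistic parameters within 5% at 2% CV over 100 seeds; qPCR folds
within 10% at σ_Ct = 0.1; efficiencies inside the observed 2–2.13 band
for a true 2.10 in ≥95% of 200 seeds) demonstrate *estimator
correctness under the assumed error model*. Real data add what the
generators deliberately omit — sampling-time jitter, baseline drift,
heteroscedastic HPLC error, plate-position effects, biological batch
variation — so passing recovery tests bounds estimator error only under
these stated assumptions.

Problem sizes used throughout the suite were chosen to keep a full run in
the order of a minute: toy LPs with ≤8 reactions against exhaustive
vertex enumeration (200 instances), one 25 h simulated fermentation for
the balance properties, and 100–200 seed recovery studies.

## 8. Known limitations

* The core model is lumped; gene-level resolution, GPR rules,
  thermodynamic constraints and flux variability analysis are out of
  scope, and genome-scale absolute flux signatures are not reproducible
  from it (section 1).
* The simulator has no pH/NH₄OH balance (pH assumed perfectly
  controlled), no hydrodynamics, and a deliberately simple foam model;
  acetate re-consumption is routed to CO₂ rather than biomass.
* The LP solver clamps infinite bounds at ±1e9 and reports solutions on
  that box as unbounded; FBA models here use finite (±1000) bounds.
* `read_sbml()` trusts the file's formulas; elemental balance is only
  enforced for the curated model, since genome-scale files routinely
  omit formulas for pseudo-species.
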