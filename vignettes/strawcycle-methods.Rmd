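---
title: "Methods: models, parameters and design choices in strawcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in strawcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawcycle)
```

# Scope and model structure

`strawcycle` models a two-stage circular cropping system.  In the
initial stage (`st`) each crop receives stage-wise irrigation `I(t)`
(mm) and seasonal nitrogen `N` (kg/ha); its straw pool is split by four
weights among field return, biochar preparation, electricity generation
and sale.  The biochar and returned straw then modify yield, quality,
per-gas emissions and carbon sequestration in the recycling stage
(`st+1`) through bivariate quadratic response surfaces.  Four system
objectives — net economic benefit (NEB), total comprehensive quality
(TCQ), water footprint (WF) and carbon footprint (CF) — are scalarized
with fuzzy linear memberships and solved as a max-min problem.

## Production model and its assumptions

Yield follows a Jensen multiplicative form per growth stage,
$Y = Y_m(N)\prod_t (ET_a(t)/ET_m(t))^{\lambda(t)}$, with the
nitrogen-limited potential $Y_m = aN^2 + bN + c$, $a < 0$.  Assumptions
worth knowing:

* **ET from the water balance.** Actual stage ET is
  $P + I + G - D - R - \Delta W$; groundwater recharge, deep seepage and
  runoff default to zero for drip-irrigated plots, and greenhouse crops
  (the first crop by default) receive zero effective rainfall because
  the greenhouse interior is assumed rain-isolated.
* **Ratio capping.** $ET_a/ET_m$ is clipped to $[0,1]$ before
  exponentiation.  The exponents reward meeting stage demand; a ratio
  above one would credit waterlogging, which the yield model has no
  mechanism to penalize otherwise.
* **Negative quadratic output.** $Y_m$ and the quality quadratic are
  floored/clipped (with warnings on the user-facing functions) rather
  than erroring, because the optimizer legitimately probes extreme
  corners of the decision box.

## Units and the amendment quadratics

All revenues and costs are carried in $10^3$ yuan per hectare and
multiplied by planted area exactly once, at aggregation; irrigation
depth converts to volume as $10\,\mathrm{m^3/ha}$ per mm.  The amendment
response surfaces $\alpha(x, y) = ax^2 + by^2 + cxy + dx + ey + f$ are
parameterized in **t/ha** of biochar ($x$) and straw ($y$) — the unit
the treatment design uses — and the objective evaluator converts the
kg/ha amounts coming out of the straw chain accordingly.  Generated
coefficient signs encode the qualitative mechanism the system is built
around: positive, saturating yield/quality responses and negative
(mitigating) responses of CO2, CH4 and N2O, all bounded on the design
range by placing the quadratic vertex beyond it.

## The straw-energy chain

Electricity comes from direct combustion
($H_v \zeta_{the} \rho_{com}\,pr_{ele} Q / 3.6$) and gasification (the
same with $\zeta_{com}\rho_{gas}$); biochar from gasification (net of an
electricity offset, floored at zero — the floor is our choice, the
model source is silent) plus pyrolysis.  Two notational repairs are
baked in: the initial-stage straw revenue is `price * pr_sell * Q`
(the printed form multiplies price by area, yield, ratio coefficients
*and* the biomass pool, which double-counts the chain that defines `Q`),
and the straw recovery coefficient appearing under two symbols is
treated as a single parameter.

## Objectives

* **NEB**: crop sales over both stages, initial-stage sale-allocated
  straw, all recycling-stage straw, and electricity sales, minus
  material (seed, fertilizer, pesticide, diesel, film, labor, purchased
  biochar/straw), electricity (lighting, irrigation pumping, rollers)
  and water costs.  Electricity revenue is credited once; recycling-
  stage generation instead offsets purchased electricity inside the
  supply constraint.
* **TCQ**: equal-stage average of crop-weighted quality scores; scores
  are clipped to $[0,1]$ (the score is interpreted on the unit
  interval; reported values in the motivating study span 0.21–0.89).
* **CF**: CO2 + 28 CH4 + 298 N2O over both stages, minus sequestration
  by crop biomass (back-calculated from grain yield via moisture,
  root–shoot ratio and harvest index), biochar and returned straw,
  per kg of total yield.  Negative values (net sink) are reported as
  such, since the definition is a signed difference.
* **WF**: green (effective rain) + blue (irrigation) + gray (nitrogen
  dilution) water per kg.  The published total-WF equation divides a
  per-kg quantity by yield a second time and repeats one symbol for all
  three components; the implementation sums the three per-kg components
  once, which is the only reading consistent with the stated units.
  Concentrations are stored in kg/m3 with an explicit mg/L converter.

## Optimization

Memberships are linear ramps anchored by a payoff table: each
objective's best anchor is its own single-objective optimum, the worst
anchor the most adverse value it takes at the other objectives' optima.
The compromise problem maximizes the minimum membership
(Zimmermann-type max-min); the solver is multistart L-BFGS-B on a
numerically stabilized soft-min surrogate (sharpness 60, which biases
the surrogate by at most $\ln(4)/60 \approx 0.023$; the reported
$\lambda$ is always the exact minimum at the returned point).
Irrigation and nitrogen bounds are native box constraints; the
electricity-supply constraint is a quadratic penalty ($10^4 \times$
squared violation).  Straw-allocation weights are fixed to a scenario
by default, matching the scenario-analysis design.  Tie-breaks among
equal-$\lambda$ optima are resolved implicitly by the deterministic
multistart order (seed-derived), so runs are reproducible.

Within one hydrological year the payoff anchors computed for the first
scenario are reused for the others.  This is deliberate: coordination
and membership comparisons across scenarios are only meaningful against
a common normalization.

A brute-force grid oracle evaluates the same scalarization exhaustively
on small instances (guarded at $2\times10^5$ points) and is used in the
tests to certify that the solver never falls below the best grid point
beyond a small tolerance.

## Uncertainty

* **Precipitation** is Pearson type III, realized as a shifted gamma
  parameterized hydrologically by (mean, Cv, Cs) with method-of-moments
  fitting; Cs = 0 degenerates to the normal limit.  Draws are strictly
  positive: when the support's lower bound is negative, non-positive
  draws are rejected and resampled (negligible mass for realistic
  parameters).  Wet/normal/dry years are the 25/50/75% exceedance
  ("guarantee rate") quantiles; classification can be Monte Carlo
  verified, giving (0.25, 0.50, 0.25) class proportions by
  construction.  Per-stage effective rainfall distributes the annual
  total by a growing-season share (0.6), an effective-rainfall
  coefficient (0.8) and mid-season-peaked stage fractions — the model
  source gives only annual totals, so this split is a documented
  modelling choice.
* **Fuzzy parameters** are triangular intuitionistic numbers
  $\langle(l,m,u); w, v\rangle$ defuzzified by
  $\frac{l+2m+u}{4}\cdot\frac{1+w-v}{2}$ — a standard accuracy/value
  index form, isolated in one function so alternatives can be swapped.
  The underlying reference formula is not printed in the model source.

## Weighting machinery

AHP uses principal-eigenvector weights with Saaty's consistency ratio
(CR < 0.1 passes).  The questionnaire step behind the published
indicator weights is replaced by configurable pairwise matrices;
scenario matrices are reconstructed from the published weights as
$w_i/w_j$ ratio matrices, which are perfectly consistent and reproduce
those weights exactly.  Entropy weights use orientation-aware min-max
normalization.  The game-theoretic combination solves the standard
least-squares Nash system $G\alpha = \operatorname{diag}(G)$ over the
Gram matrix of candidate weightings, normalizing $\alpha$ and falling
back to equal coefficients when the system is singular (identical
candidates) — the source's exact combination formulas live in an
unavailable supplement, so the standard formulation from the
combination-weighting literature is used.

## Coordination and validation

Scenario comparison normalizes the four objectives min-max across the
compared set (footprints inverted so larger is better) and computes the
coupling coordination degree $C = (\prod u / \bar u^k)^{1/k}$,
$T = \sum\beta u$, $D = \sqrt{CT}$.  The grade bands (advanced ≥ 0.8,
secondary 0.6–0.8, marginal 0.4–0.6, else imbalanced) are configurable
because published threshold labels vary.  Model agreement uses $R^2$,
nRMSE and the Willmott consistency index.

## What the synthetic generator does and does not establish

The generator reproduces the *structure* the analysis assumes: the
nine-treatment irrigation × nitrogen × additive Latin square with three
replicates, concave quadratic N and quality responses with vertices at
the recommended rates, bounded amendment quadratics, published
stage-sensitivity exponents for the default three crops, a skewed
annual precipitation climate, and multiplicative Gaussian observation
noise truncated at zero (field measurements are strictly positive; the
error model itself is our choice, none is published).  Replicates share
treatment-level truth and differ only in noise.

What it does **not** emulate: soil-physics dynamics, real market price
series, spatial heterogeneity, or the actual fitted coefficient values
of the motivating study (those are unpublished; the drawn ranges are a
stand-in, not estimates).  A green test therefore establishes internal
correctness — recovery of generating coefficients, solver optimality
against the oracle, invariant preservation, directional scenario
ordering — not numeric agreement with the study's headline results,
which are out of reach by construction.

Because the Latin square confounds additive level with (I, N), the
six-coefficient amendment surface is not identifiable from the
nine-treatment design; a dedicated full-rank 3 × 3 biochar × straw
design (`generate_amendment_design()`) exists for that purpose, while
the N response is recovered from the standard design.

## Numerical choices

* Solver tolerances: L-BFGS-B `factr = 1e9` (about 2 × 10^-7 relative),
  feasibility slack 10^-6; allocation simplex tolerance 10^-9.
* Memberships are evaluated unclipped inside the solver (clipping
  destroys the gradient outside the ramp) and clipped for reporting.
* Degenerate payoff anchors (best = worst) are widened by
  max(10^-6, 1%) on the worst side.
* Config files are JSON (via jsonlite) rather than YAML: the deployment
  environment guarantees a JSON parser but not a YAML one, and the
  schema is flat enough that nothing is lost.
* Crop quality weights may differ by stage in the TCQ definition; the
  implementation accepts stage-specific weights with a shared default,
  since the source does not say whether they differ.
* Hydrological classification supports both calendar-year totals and
  season-cumulative rainfall (via the numeric form of
  `hydro_scenario()`), as the source is ambiguous about which it used.
* The irrigation-water share `a` in the electricity-supply constraint
  is implemented as printed (`AP <= a * TAE`) with `a` configurable in
  (0, 1].
* Field capacity 30.54% and wilting point 12.72% are published as mass
  ratios; the irrigation-quota formula expects volumetric fractions, so
  conversion via bulk density (1.20 g/cm3) is left to configuration and
  the packaged defaults already store volumetric values.

## Known limitations

Joint (not sequential) optimization of both stages is assumed; no
global-optimality certificate is claimed (multistart + oracle spot
checks instead); transport logistics and plant-level engineering of the
energy conversion chain are out of scope; market dynamics, subsidies
and discounting are excluded; the NEB scale of synthetic instances
depends on generator price/usage defaults and should not be read as a
prediction for any real system.
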