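---
title: "Envirome-guided projection to latent pathways: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envirome-guided projection to latent pathways: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plpath)
```

## The model

A metabolic network at (quasi) steady state constrains every achievable
flux vector `r` to the cone spanned by its elementary flux modes (EMs):
`r = E λ` with `λᵢ ≥ 0` for every mode containing an irreversible
reaction, and `λᵢ` free for *fully reversible* modes (those whose support
is entirely reversible, so the negated mode is equally valid). `plpath`
adopts the working hypothesis that the *structure* `E` is set by the
genome while the *weights* `λ(t)` are, to a useful approximation, affine
functions of the measured environment `x(t)` — temperature, pH,
osmolality, extracellular concentrations. Under that hypothesis, paired
observations `(X, R)` of envirome state and specific exchange rates let us
ask which few modes the environment is actually driving, and how.

Two assumptions deserve emphasis. First, *quasi steady state within a
phase*: specific rates are treated as constant inside each metabolic phase
of a culture, which is why phase segmentation precedes everything else.
Second, *linearity of the weight response*: a mode weight is modelled as
intercept plus a linear combination of scaled envirome factors. This is a
first-order description of what is certainly a saturating, interacting
regulatory system; the fitted coefficients are statistical associations,
not mechanisms, and nothing in the package should be read as causal.

## The selection algorithm

`plp_fit()` is partial least squares with the output loadings pinned to
elementary modes. Candidate modes enter with unit Euclidean norm over the
measured fluxes, so selection is invariant to how modes are scaled.
Selection is greedy, one latent pathway per step:

1. For the selected set `S` plus one candidate `e`, fit all weights jointly
   as affine functions of the scaled envirome and evaluate the explained
   flux sum of squares. Both projections are closed form —
   `R̂ = P_X R P_E`, with `P_X` the hat matrix of `[1 X]` and `P_E` the
   projector onto the candidate mode span — so the score of a candidate is
   `tr(M P_E)` with `M = (P_X R)'(P_X R)` computed once.
2. Add the maximizer; ties go to the lowest mode index.
3. Stop at `max_components` (default 20) or when the best remaining gain
   falls below `min_variance_gain` (default 0.5 percentage points of
   explained variance).

An earlier design extracted one NIPALS direction per mode and deflated `R`
by a rank-one term. We replaced it after it failed the package's own
noise-free requirement: with non-orthogonal modes, successive rank-one
deflations are alternating projections that approach — but never reach —
the span of the active modes, and a single latent direction cannot
represent an affine weight exactly. The joint-regression score keeps the
one-mode-per-component ranking semantics, makes the first selection
exactly the mode of maximum single-mode explained variance, guarantees a
non-decreasing cumulative-variance trajectory, and is exact (100% ± 1e-6)
when the data are noise-free and the weights truly affine. The per-mode
intercept plays the role that response centring plays in ordinary PLS: it
absorbs the envirome-independent part of a weight so that only
envirome-correlated variation competes for components.

Sign handling follows the flux-cone geometry. Irreversible-containing
modes are only meaningful with non-negative weights; they always report
sign +1, and a *fitted* weight trajectory dipping negative (visible in
`Lambda_hat`) is a diagnostic that the mode is being used to mop up
variance rather than describe a pathway. A fully reversible mode spans the
same line in either orientation, so the variance score cannot distinguish
`+e` from `−e`; its reported sign is the sign of its mean fitted weight,
and a `−` in the ranking reads "this pathway ran in reverse in this
window".

`X` is autoscaled by default (per-column mean 0, variance 1) so that
factors with different units compete fairly; zero-variance columns are
kept, flagged, and receive zero coefficients. `R` is fitted in rate units
— scaling the response would break `R = Λ E'`. Fitted weights are reported
on the canonical mode scale (smallest nonzero coefficient equal to 1,
matching how macroscopic reactions are usually written), and the
functional enviromics map is the coefficient matrix on that scale; its
variance-scaled copy multiplies each column by the mode's incremental
explained-variance share so that visually dominant columns are also
variance-dominant ones.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| `min_variance_gain` | `plp_config()` | 0.5 (% points) | stop when the best candidate adds less |
| `max_components` | `plp_config()` | 20 | hard cap on selected modes |
| `alpha` | `mfa_wls()`, `plp_fit_consistent()` | 0.05 | χ² significance of the consistency test (the level is not fixed by precedent; it is configurable) |
| relative sds | `error_model()` | 5% named / 10% default | measurement error model: 5% suits enzymatic assays (glucose, lactate, glutamine, glutamate, ammonia), 10% HPLC/ELISA analytes |
| sd floor | `error_model()` | 1e-6 rate units | keeps near-zero rates from receiving infinite weight |
| `f_threshold` | `segment_phases()` | 30 | F statistic a split must exceed; at 30 a single-kink profile with 2% noise is recovered within one sampling interval without phantom splits |
| `max_modes` | `enumerate_ems()` | 1e6 | combinatorial-explosion guard |

## Metabolic flux analysis and the consistency index

`mfa_wls()` partitions fluxes into measured and unknown, requires the
unknown block to be determined (`rank(S_u)` equal to the number of
unknowns — otherwise it asks for more measurements), and projects the
balances onto the left null space of `S_u` to obtain the redundancy
equations `Rr v_m = 0`. Measurements are reconciled by the standard
variance-weighted update, and the consistency index is the weighted
residual quadratic form `h = ε'(Rr F Rr')⁺ε`, χ²-distributed with
`rank(Rr)` degrees of freedom under the null of correct stoichiometry and
Gaussian errors. Degrees of freedom come from the rank, not the row count,
so degenerate networks (duplicated balances) are handled. The
null-space/pseudo-inverse route was chosen over a Lagrange solve for
numerical robustness on reduced networks, whose balanced matrices are
often rank-deficient after reactions are removed.

`plp_fit_consistent()` uses this test as a stopping rule: grow the
selection one mode at a time, reduce the network to reactions appearing in
any selected mode (removal is equivalent to a null-flux constraint;
orphaned metabolites are dropped so the matrices stay full rank), and stop
at the first reduction whose MFA is consistent.

## Baselines and their normalization

`min_norm_weights()` implements the minimum-norm decomposition: hard mode
enforces `Eλ = r` exactly; soft mode (the default for measured rates) is
lexicographic — first minimise the residual, then the weight norm among
minimisers to 1e-8. `alpha_spectrum()` computes per-mode LP bounds of the
feasible weights. Both operate on whatever scaling `E` carries; thresholds
like 0.1 or 1.0 in `weight_census()` are therefore meaningful only
relative to the canonical mode scaling, which is stated here because the
threshold semantics are otherwise ambiguous. Redundant balance rows are
reduced by QR pivoting before the QP/LP solves (solutions are re-verified
against the full system), and fully reversible modes enter the programs
with free sign.

The qualitative contrast the package demonstrates — minimum-norm
decompositions are *denser* than PLP selections — only exists where the
decomposition is non-unique. On compound-level exchange rates (one rate
per extracellular compound, the realistic measurement) a route-redundant
network has `rank(E_ext)` far below `nem`, the QP spreads weight over many
modes, and PLP keeps only the envirome-correlated ones. On
reaction-resolved rates the decomposition can be unique and the contrast
disappears; the tests use a two-layer routed network projected onto its
four external compounds for exactly this reason.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the method assumes: smooth
envirome trajectories (depleting substrates with threshold-triggered feed
ramps, a pH trace confined to the controlled 7–7.25 band, near-constant
temperature, drifting osmolality), weights affine in the scaled factors
with intercepts lifted so irreversible-mode weights stay positive in the
linear regime, and multiplicative log-normal measurement noise at 5–10%
relative sd — the error magnitudes typical of enzymatic and HPLC assays.
`simulate_culture()` integrates the amount balances forward with `deSolve`
and feeds `estimate_specific_rates()` its own output for round-trip
checks. Every generator is a pure function of its arguments and seed.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: saturating or switching regulation
(weights are exactly affine), correlated measurement errors across
analytes, sampling irregularity and missing values, cell lysis and
viability decline, and the strong collinearity of envirome factors that
co-vary under a shared feeding policy (the generator produces some
collinearity through shared feed events, but real cultures are worse).
Parameter recovery at 5% noise in the benchmarks is a statement about the
estimator under its own assumptions, not about BHK biology.

Rate estimation works on amounts (`V·C`), not concentrations, so
feed/dilution terms cancel exactly; units are mM and mL in, nmol per 10⁶
cells per hour out (consumption negative). The specific growth rate is
fitted by log-linear regression of *total* viable cells `Xv·V` rather than
density: under fed-batch dilution the density slope underestimates growth,
while for a batch the two coincide.

## Numerical choices

* Rank and pseudo-inverse thresholds: singular values below
  `1e-10·σ_max` are treated as zero throughout.
* Stoichiometric coefficients below 1e-12 are zeroed at load; mode
  coefficients below `1e-9·max` after back-substitution.
* Enumeration: double description on the reversibility-split cone with the
  combinatorial adjacency (support-minimality) test; spurious
  forward/backward two-cycles vanish on recombination; ± copies of fully
  reversible modes merge under canonical orientation (first nonzero entry
  positive). Output order is lexicographic by support with the first
  nonzero coefficient as tie-break, so runs are byte-reproducible.
* Network compression merges a strictly coupled pair only when the shared
  metabolite's two coefficients have opposite signs (positive flux ratio);
  same-sign pairs are removed when both reactions are irreversible (both
  dead) and left uncompressed otherwise. This keeps the
  compress-enumerate-expand path exactly equal to direct enumeration.
* Degenerate PLP inputs fail fast with specific errors: all-zero `R`,
  empty mode set, fewer than two observations, unknown measured ids.
* The QP lower bound for sign-free variables is a large finite box (±1e9)
  because the active-set solver rejects infinite bounds; the LP adds a
  `sum(x) ≤ 1e8` box so that solver failure cleanly separates
  infeasibility from unboundedness.

## Problem sizes in the test bench

The suite and the acceptance script run, with fixed seeds: oracle
cross-checks on 50 random networks of 6–12 reactions (exhaustive
support-subset enumeration is exponential, hence the size cap);
planted-mode recovery on a 20-mode universe with 3 active modes, 100
observations, 27 factors, 5% noise, 100 replicates; consistency-test
calibration with 10,000 Monte-Carlo replicates at 2 degrees of freedom;
density contrasts over 20 replicates of 25 observations. These sizes make
the whole bench run in well under a minute while keeping Monte-Carlo
error comfortably inside the asserted tolerances (e.g. ±1.5 percentage
points on a 5% rejection rate at n = 10⁴).

## Known limitations

* Enumeration is exact but not engineered for genome-scale networks; the
  double-description implementation is comfortable to a few hundred modes
  and guarded by `max_modes` beyond that.
* The FEM inherits every caveat of linear regression on collinear
  predictors: coefficients of co-varying factors are not individually
  identifiable, and intervention claims need designed experiments.
* The consistency stopping rule tests the *reduced network* against
  phase-mean rates; it does not localize which measurement carries a gross
  error (serial elimination is out of scope).
* The full BHK network and its 251-mode list are referenced but not yet
  transcribed from the original study's supplementary files;
  `load_fixture()` reports them as pending, and analyses specific to that
  network (mode counts, the product-mode stoichiometry) are not
  reproduced here. The packaged fixtures carry the printed phase-rate
  table, operating conditions, and phase-wise selections, which are
  sufficient for the conservation statistics.
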