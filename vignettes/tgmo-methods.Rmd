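---
title: "Methods: therapeutically guided multidrug optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: therapeutically guided multidrug optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgmo)
```

This vignette is the package's account of the statistical method it
implements, the assumptions behind each stage, and the design choices made
where the method leaves the implementation open.

## The problem and the search loop

A panel of k candidate drugs (here up to 13) is to be reduced to a small
combination that kills cancer cells at low, clinically realistic doses
while sparing a non-malignant reference line. Exhaustive dose-combination
screening is infeasible, so the search is iterative:

1. **Dose selection.** Each drug's monotherapy dose–response is fitted and
   the dose producing 20% inhibition (IC20) is chosen as the screening
   dose — low enough that combination effects, not single-drug potency,
   dominate the screen. Doses are capped at the clinically used dose
   (CUD), a plasma-exposure-derived ceiling: if the IC20 exceeds the CUD
   or the curve is flat, the CUD is used.
2. **Design.** An orthogonal array composite design (OACD) assigns each
   drug one of three coded levels per run: 0 (absent), 1 (half dose),
   2 (screening dose).
3. **Measurement.** Each design run is measured in the cancer line(s) and
   the normal line, in replicate (default N = 3), as percent viability of
   the vehicle control.
4. **Modelling.** Each endpoint — cancer viability and the therapeutic
   window TW = viability(normal) − viability(cancer) — is regressed on the
   coded levels with a second-order model. Significant coefficients are
   classified by sign: on the cancer endpoint negative is beneficial
   (more kill); on TW positive is beneficial (more selectivity). A
   significant positive interaction on the cancer endpoint is antagonism;
   a significant negative one is synergy.
5. **Elimination.** Drugs are scored by their detrimental evidence and up
   to three are removed per round; the loop repeats on the reduced panel.
6. **Refinement.** Once at most four drugs remain, a final round compares
   the current doses against escalated doses (doubled, capped at the CUD)
   and emits the optimized combinations.

## Dose–response stage

The monotherapy model is the fixed-asymptote variable-slope logistic
(4PL with top 100, bottom 0):

$$v(c) = \frac{100}{1 + (c/\mathrm{IC}_{50})^h},$$

fitted in log10-dose space by Levenberg–Marquardt least squares. We call
the optimizer core (`minpack.lm::nls.lm`) on the residual function
directly rather than through the `nls` model-object machinery, because the
latter can fail on noiseless data when an iterate lands exactly on the
generating parameters; a small ladder of four starting points guards
against local minima, and the best converged fit by deviance is kept.
Bounds are h ∈ (0.1, 10] and log10 IC50 ∈ [−6, 6] (µM scale), wide enough
to be inert for any realistic screen but preventing runaway estimates on
degenerate data.

The IC20 has the closed form IC50 · (20/80)^(1/h), and `invert_to_icf()`
evaluates it for any inhibition level f ∈ (0, 100).

**Flatness rule.** No criterion for "flat" is standard, so the package
flags a curve flat when the fit explains less than half the response
variance (R² < 0.5) or the fitted IC50 extrapolates more than 10× beyond
the largest tested dose; both thresholds are arguments of `fit_4pl()`.
Flat curves are never inverted — the CUD is used instead.

**Level-1 dose.** The three-level design needs a second nonzero dose; the
package uses half the screening dose. Any fixed ratio in (0, 1) would
serve; one half keeps the levels evenly spaced on the raw concentration
scale, matching the coded-level spacing used in the regression.

## The composite design

The OACD is the union of three blocks:

* a **two-level block** at coded levels {0, 2}: the full 2^k factorial for
  k ≤ 4, otherwise a regular fraction of resolution at least V found by a
  deterministic greedy search over the effect columns of a 2^m full
  factorial (a column set is resolution ≥ V exactly when all pairwise
  XOR products are nonzero, mutually distinct, and distinct from the
  chosen columns). Resolution V keeps every main effect and two-factor
  interaction unaliased with any other, which is what lets the full
  second-order model reach full column rank — a resolution-IV fraction
  would leave the k = 10 model matrix (66 columns) short of rank;
* a **three-level block** at levels {0, 1, 2} supplying curvature: the
  full 3^k for k ≤ 3, the OA(18, 3^7) array for k ≤ 7, and an
  OA(27, 3^13) built from the GF(3) linear forms over three base columns
  for k ≤ 13;
* one **all-zero center run**, the vehicle condition.

Duplicate runs across blocks are collapsed (first occurrence kept,
multiplicity recorded) and the measurement order is shuffled
reproducibly by the seed. `validate_design()` reports the numeric rank of
the requested model matrix, the level balance of the constructed
three-level array, the maximum pairwise column correlation, and the
D-efficiency det(XᵀX)^(1/p)/n of the standardized model matrix. Balance is
a property of the array as designed, so it is computed on the stored
three-level block rather than on the deduplicated run list.

## Regression stage

The model for each endpoint is the full quadratic response surface in the
coded levels,

$$y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
\sum_{i<j} \beta_{ij} x_i x_j + \varepsilon,$$

with p = 1 + 2k + k(k−1)/2 candidate columns. Numerical choices:

* **Centering, not standardization.** Levels are centered before products
  are formed, and the square/product columns are re-centered. This
  removes most intercept–quadratic collinearity while keeping
  coefficients in interpretable per-coded-level units.
* **Replicate rows enter individually**, preserving the error degrees of
  freedom that the stepwise p-values rely on; conditions are never
  pre-averaged.
* **Selection** is bidirectional stepwise from the intercept-only model:
  the candidate with the smallest partial-F p-value enters while below
  `p_enter` (default 0.05); after each entry, included terms whose
  p-value exceeds `p_remove` (default 0.10) are dropped, worst first.
  These defaults are the conventional ones for p-value-driven stepwise
  selection. Term hierarchy is deliberately not enforced — an interaction
  may stay without its main effects, since interaction structure is
  exactly what the method acts on. Candidates numerically collinear with
  the current model are skipped and logged. Entry stops when the residual
  sum of squares is numerically zero (an exact fit), which otherwise
  produces unstable infinite F statistics on noiseless data.
* **Outliers.** Cook's distance is computed for every observation of the
  selected model; rows above three times the mean distance are removed in
  a single pass and the same term set is refitted once. The classic 4/n
  cutoff is available as an option. No iteration: repeated trimming on
  clean data would walk through the χ²-like tail of the distance
  distribution indefinitely. If removal would leave fewer rows than
  columns, nothing is removed.
* **Diagnostics** are computed on the post-removal fit: R², adjusted R²,
  residual RMSE, the overall-model ANOVA F-test p-value, and the Pearson
  correlation between fitted and observed values (whose square equals R²
  for any OLS fit with an intercept — checked as a test invariant).

## Classification, the ledger, and elimination

Every non-intercept term of a fitted model is classified **beneficial**,
**detrimental**, or **neutral**: neutral when p ≥ `alpha_sig` (default
0.05, matching the entry threshold), otherwise by the endpoint's sign
convention. The per-drug ledger then collects, across endpoints:
significant detrimental and beneficial interactions the drug participates
in, detrimental and beneficial linear main effects, the monotherapy
effect at the level-2 dose, and toxicity alone — normal-line viability
below 80% of control, measured on dedicated monotherapy arms that
accompany each round's design (the OACD blocks themselves need not
contain single-drug runs).

The elimination score is

score = w₁ · (detrimental interactions) + w₂ · (toxic alone) +
w₃ · (detrimental mains), with default weights (1, 2, 1).

Toxicity is weighted double because a drug harmful to the normal line
disqualifies itself regardless of its combination behaviour. Up to
`max_removals` (default 3) drugs with strictly positive scores are
removed per round, highest score first; ties are resolved by the weaker
monotherapy effect (higher viability alone), then drug name, making the
ranking fully deterministic. The toxicity boundary applies strictly below
80: a viability of exactly 80.0 is non-toxic (the threshold and the
strictness are configurable).

## Convergence and the final round

Elimination rounds continue while more than four drugs are active. If a
round removes nothing while more than four drugs remain, the four with
the best beneficial evidence (non-toxic first, most significant
beneficial terms, strongest monotherapy) are enrolled. Once at most four
drugs are active the search converges and the final dose-refinement round
runs: the enrolled set is measured both at the current doses and at
escalated doses (each level-2 dose doubled, capped at its CUD — drugs
already at the CUD are unchanged), and the variant with the larger
full-combination therapeutic window is carried forward.

Combinations are then emitted from the chosen variant:

* a drug is **eligible** if it is non-toxic alone and shows some
  significant beneficial evidence;
* antagonism is judged on the cancer endpoint: each significant positive
  interaction among eligible drugs is resolved by dropping the member
  with the lesser beneficial contribution (fewer beneficial
  interactions, then fewer beneficial mains, then the weaker
  monotherapy). Dropping one member per flagged pair, rather than both,
  keeps a spurious flag from costing two drugs;
* the **combined** combination is the eligible set (≥ 2 drugs); the
  **synergistic** variant is the union of significantly synergistic
  pairs; the **additive** variant is the largest set of drugs with
  beneficial main effects and no significant interactions among
  themselves — when a pair inside the candidate set does interact, the
  member with the weaker cancer main effect is dropped. Duplicate member
  sets are emitted once.

If no drug carries beneficial evidence the search reports failure with
reason "no beneficial terms" and emits nothing. Every emitted dose is at
or below the CUD by construction, and no drug flagged toxic alone in its
final round can appear in a combination — both are asserted as test
invariants.

With several cancer lines the search runs independently per line against
the shared normal line; ledgers are not merged across lines.

## The synthetic screen

The simulator provides the ground truth the test suite measures recovery
against. Monotherapy responses follow Hill curves per drug and line;
a run's expected viability fraction is

$$V = \Big(\prod_i v_i(c_i)\Big) \cdot
\exp\Big(\sum_{i<j} \psi_{ij}\, a_i a_j\Big),$$

where $a_i = 1 - v_i(c_i)$ is the inhibited fraction. With all
$\psi = 0$ this is Bliss independence; negative $\psi$ lowers combination
viability (synergy), positive raises it (antagonism), smoothly and
boundedly because the modifier acts on the log scale weighted by the
activity product. Reported values are 100 · V plus Gaussian noise
(default σ = 5 viability points, a plausible replicate scatter for
ATP-based plate readouts), truncated at 0 but not at 100 — luminescence
readouts can exceed the vehicle mean. Noiseless simulations are exact
closed-form evaluations and bit-reproducible.

One consequence of simulating under Bliss independence deserves emphasis:
on the percent scale the Bliss product itself curves upward —
$v_i v_j = 1 - a_i - a_j + a_i a_j$ — so two active, *independent* drugs
show a small positive interaction coefficient of order
$100 \cdot a_i a_j$ in the linear-model sense. Bliss-additivity and
regression-additivity are different nulls. The scripted scenario
(`make_rcc_scenario()`) therefore defines its "additive" survivor
quartet as additive on the percent scale, which under the Bliss formula
corresponds to a small negative $\psi$ (≈ −8 here, calibrated by zeroing
the noiseless interaction coefficients at the refinement doses) rather
than $\psi = 0$. Planted antagonisms (+18) and the planted synergy (−26)
are an order of magnitude stronger, so their regression signatures
(|β| ≈ 2–6 viability points against standard errors of ≈ 0.3–0.7) carry
the sign of $\psi$ — a property the tests verify.

The scenario plants: three drugs that are antagonistic among themselves
and frankly toxic to the normal line (eliminated in round 1); three more
antagonistic drugs (eliminated in round 2); a synergistic pair
(MET-inhibitor-like and GLS1-inhibitor-like) and two additive partners
that survive to the final round. Monotherapy effects are mild (7–12%
inhibition at the screening dose), as IC20-targeted dosing intends.

What the simulator does **not** emulate: plate-position effects, batch
drift between independent experiments, heteroscedastic noise at low
viability, receptor-level mechanism, hypoxia, or 3D-culture behaviour.
Passing recovery tests therefore demonstrates that the analysis correctly
inverts the data-generating process it assumes, not that it is robust to
every artefact of real plates.

## Problem sizes in the test suite and acceptance script

The suite exercises the pipeline at the sizes the method is designed for:
designs up to k = 13 (rank checks), power and type-I calibration at 200
simulated screens on the k = 4 and k = 3 designs with N = 3 replicates
and σ = 5, and 50 (tests) / 25 (acceptance script) end-to-end runs of the
ten-drug scenario. These sizes give stable Monte-Carlo estimates of the
recovery rates while keeping a full run of the suite in the one-minute
range on a single core.

## Known limitations

* Stepwise selection inflates the significance of selected terms; the
  package reports the post-selection OLS p-values, as the method
  prescribes, and the false-antagonism rate this produces is what the
  pair-resolution rule in the final round is designed to absorb.
* The therapeutic-window endpoint pairs cancer and normal replicates by
  index to form per-replicate differences; replicates are independent
  plates, so this adds (not cancels) their noise.
* The regression treats replicate rows as exchangeable; experiment-level
  random effects are out of scope.
* Combination-index (Chou–Talalay) analysis, mixture designs and
  D-optimal augmentation are out of scope; the design provider is
  swappable if another array family is needed.
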