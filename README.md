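# tgmo

Therapeutically guided multidrug optimization (TGMO) for cell-based
combination screens, as a tidyverse-style R package.

Finding an effective low-dose drug combination among 10 candidate drugs is
a search over an enormous dose space: even three dose levels per drug give
3^10 ≈ 59,000 combinations. TGMO replaces exhaustive screening with a
design-of-experiments loop: a small orthogonal array composite design
(OACD) of combinations is measured in a cancer line and a non-malignant
line, a second-order regression deconvolutes the measured viabilities into
single-drug effects and drug–drug interactions, and drugs showing
antagonism or toxicity are eliminated. After a few rounds the search
converges on an optimized drug combination (ODC) of at most four drugs,
each dosed at or below its clinically used dose (CUD).

The package is written for computational scientists in drug-combination
screening who want the full pipeline as tested, composable functions:

* **plate handling** — normalization of raw viability signal to the
  vehicle control, replicate aggregation, toxicity flagging against the
  80%-viability threshold (`normalize_to_vehicle()`,
  `aggregate_replicates()`, `flag_toxicity()`);
* **dose selection** — variable-slope logistic dose–response fits with
  fixed asymptotes, `v(c) = 100 / (1 + (c/IC50)^h)`, IC20 extraction by
  the closed form `IC20 = IC50·(20/80)^{1/h}`, and CUD capping
  (`fit_4pl()`, `invert_to_icf()`, `select_screen_dose()`);
* **designs** — OACD construction (resolution-V two-level fraction ∪
  three-level orthogonal array ∪ center run) with estimability, balance
  and D-efficiency diagnostics (`generate_oacd()`, `validate_design()`);
* **modelling** — centered second-order model
  `y = β₀ + Σβᵢxᵢ + Σβᵢᵢxᵢ² + Σβᵢⱼxᵢxⱼ + ε` fitted by p-value-driven
  bidirectional stepwise OLS, with Cook's-distance outlier handling and
  ANOVA/R²/RMSE diagnostics (`stepwise_fit()`, `cooks_filter()`); the
  endpoints are cancer viability and the therapeutic window
  `TW = viability(normal) − viability(cancer)` (`compute_tw()`);
* **optimization** — sign-convention term classification (on cancer
  viability a negative coefficient is beneficial; on TW a positive one
  is), per-drug evidence ledgers, scored elimination, dose escalation
  under the CUD cap, and the multi-round orchestrator
  (`classify_terms()`, `eliminate_drugs()`, `refine_doses()`,
  `tgmo_run()`);
* **synthetic screens** — a Bliss-independence simulator with planted
  pairwise interactions and Gaussian plate noise, providing ground truth
  for every stage (`simulate_bliss()`, `make_rcc_scenario()`).

Fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

The scripted ten-drug renal-carcinoma scenario plants three toxic,
mutually antagonistic drugs (removed in round 1), three more antagonistic
drugs (removed in round 2), one synergistic pair and two additive partners
among the survivors:

```r
library(tgmo)

truth <- make_rcc_scenario(noise_sd = 5)   # plate noise: 5 viability points
res <- tgmo_run(make_measure_fn(truth), rcc_drug_table(),
                cancer_lines = "786O", normal_line = "RPTEC", seed = 7)
res
#> <tgmo_search> converged
#>   786O: 3 round(s), status converged
#>   optimized combinations:
#> # A tibble: 9 × 5
#>   cell_line odc             type        drug          dose_uM
#>   <chr>     <chr>           <chr>       <chr>           <dbl>
#> 1 786O      ODC_combined    combined    crizotinib      0.664
#> 2 786O      ODC_combined    combined    telaglenastat   0.013
#> 3 786O      ODC_combined    combined    U-104           9.52
#> 4 786O      ODC_combined    combined    vismodegib     12.8
#> 5 786O      ODC_synergistic synergistic crizotinib      0.664
#> 6 786O      ODC_synergistic synergistic telaglenastat   0.013
#> 7 786O      ODC_additive    additive    telaglenastat   0.013
#> 8 786O      ODC_additive    additive    U-104           9.52
#> 9 786O      ODC_additive    additive    vismodegib     12.8

search_trace(res)
#> # A tibble: 3 × 4
#>   cell_line round     k removed
#>   <chr>     <int> <int> <chr>
#> 1 786O          1    10 "axitinib;aspirin;osimertinib"
#> 2 786O          2     7 "palbociclib;simvastatin;selumetinib"
#> 3 786O          3     4 ""
```

Reading the output: rounds 1–2 eliminate the six planted detrimental
drugs, three per round, exactly as scored by their significant
antagonistic interactions and normal-line toxicity. The final round keeps
the quartet, escalates doses under the CUD cap (crizotinib is already at
its CUD of 0.664 µM and stays there; vismodegib doubles to 12.754 µM,
a 1.3-fold margin below its 17 µM CUD), and emits three combination
variants: the full four-drug set, the synergistic crizotinib +
telaglenastat core (their interaction coefficient is significantly
negative on cancer viability, i.e. synergy), and a purely additive triple
whose members show beneficial main effects and no significant
interactions among themselves. All emitted doses are at or below the CUD
and no drug toxic to the normal line survives into a combination.

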