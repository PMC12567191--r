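fake_model <- function(endpoint, terms) {
  structure(list(endpoint = endpoint, terms = terms), class = "tgmo_model")
}

term_row <- function(label, kind, i, j, beta, p) {
  tibble::tibble(label = label, kind = kind, i = i, j = j,
                 beta = beta, se = abs(beta) / 5, p_value = p)
}

test_that("term classification follows the endpoint sign conventions", {
  tt <- dplyr::bind_rows(
    term_row("(Intercept)", "intercept", NA_integer_, NA_integer_, 90, 0),
    term_row("a:b", "interaction", 1L, 2L, 6, 0.01),
    term_row("a", "linear", 1L, NA_integer_, -4, 0.001),
    term_row("b", "linear", 2L, NA_integer_, 2, 0.5))
  cancer <- classify_terms(fake_model("cancer_viability", tt))
  expect_equal(cancer$call[cancer$term == "a:b"], "detrimental")  # antagonism
  expect_equal(cancer$call[cancer$term == "a"], "beneficial")
  expect_equal(cancer$call[cancer$term == "b"], "neutral")
  tw <- classify_terms(fake_model("therapeutic_window", tt))
  expect_equal(tw$call[tw$term == "a:b"], "beneficial")
  expect_equal(tw$call[tw$term == "a"], "detrimental")
  expect_false("(Intercept)" %in% cancer$term)
})

make_ledger <- function(n = 10, det_int = rep(0, n), toxic = rep(FALSE, n),
                        det_main = rep(0, n), mono = rep(85, n)) {
  out <- tibble::tibble(
    drug = sprintf("drug%02d", seq_len(n)),
    monotherapy_effect = mono,
    normal_viability = ifelse(toxic, 70, 95),
    toxic_alone = toxic,
    detrimental_interactions = det_int,
    beneficial_interactions = 0L,
    detrimental_mains = det_main,
    beneficial_mains = 1L)
  class(out) <- c("drug_ledger", class(out))
  out
}

test_that("drug elimination ranks by detriment score with stable tie-breaks", {
  led <- make_ledger(10,
                     det_int = c(4, 0, 3, 0, 2, 0, 0, 1, 0, 0),
                     toxic = c(rep(FALSE, 9), TRUE))
  res <- eliminate_drugs(led, max_removals = 3)
  # scores: d01=4, d03=3, d05=2, d10=2(toxicity), d08=1 -> top three, ties
  # broken by weaker monotherapy then name (d05 before d10 on equal mono)
  expect_equal(res$removed, c("drug01", "drug03", "drug05"))
  expect_true(all(res$ledger$reasons[res$ledger$drug %in% res$removed] != ""))
  # nothing detrimental: the search converges with an empty removal set
  expect_equal(eliminate_drugs(make_ledger(5))$removed, character(0))
  expect_error(eliminate_drugs(make_ledger(2)),
               class = "tgmo_validation_error")
})

test_that("toxicity outweighs a single interaction under default weights", {
  led <- make_ledger(4, det_int = c(1, 0, 0, 0),
                     toxic = c(FALSE, TRUE, FALSE, FALSE))
  res <- eliminate_drugs(led)
  expect_equal(res$removed[1], "drug02")  # weight 2 beats count 1
})

test_that("dose refinement doubles within the clinical cap", {
  specs <- drug_specs(c("vismodegib", "crizotinib", "telaglenastat"),
                      cud_uM = c(17.000, 0.664, 2.113),
                      screen_dose_uM = c(6.377, 0.664, 0.0065))
  ref <- refine_doses(specs)
  expect_equal(ref$screen_dose_uM, c(12.754, 0.664, 0.013))
  expect_equal(ref$half_dose_uM, ref$screen_dose_uM / 2)
  expect_true(all(ref$screen_dose_uM <= ref$cud_uM))
})

test_that("the scripted search recovers the planted structure end to end", {
  truth <- make_rcc_scenario()
  res <- quiet(tgmo_run(make_measure_fn(truth), rcc_drug_table(),
                        cancer_lines = "786O", normal_line = "RPTEC",
                        seed = 2))
  expect_equal(res$status, "converged")
  tr <- search_trace(res)
  removed <- unlist(strsplit(tr$removed, ";"))
  planted <- c("aspirin", "axitinib", "osimertinib",
               "simvastatin", "selumetinib", "palbociclib")
  expect_setequal(intersect(removed, planted), planted)
  # final active set is the surviving quartet
  expect_equal(nrow(res$searches[["786O"]]$rounds[[3]]$specs), 4)
  # synergistic pair and additive variant both surface
  expect_true(all(c("combined", "synergistic", "additive") %in%
                    res$odcs$type))
  syn <- res$odcs$drug[res$odcs$type == "synergistic"]
  expect_setequal(syn, c("crizotinib", "telaglenastat"))
  add <- res$odcs$drug[res$odcs$type == "additive"]
  expect_true(length(add) >= 2 && !"crizotinib" %in% add)
  # safety and dose-cap invariants on everything emitted
  tbl <- rcc_drug_table()
  cud <- setNames(tbl$cud_uM, tbl$drug)
  expect_true(all(res$odcs$dose_uM <= cud[res$odcs$drug] + 1e-9))
  expect_false(any(res$odcs$drug %in% planted))
})

test_that("reruns with the same seed reproduce the search identically", {
  truth <- make_rcc_scenario()
  r1 <- quiet(tgmo_run(make_measure_fn(truth), rcc_drug_table(),
                       cancer_lines = "786O", normal_line = "RPTEC",
                       seed = 4))
  r2 <- quiet(tgmo_run(make_measure_fn(truth), rcc_drug_table(),
                       cancer_lines = "786O", normal_line = "RPTEC",
                       seed = 4))
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("an inert truth converges to an empty combination", {
  drugs <- sprintf("d%01d", 1:5)
  hill <- tidyr::expand_grid(drug = drugs, cell_line = c("ca", "no"))
  hill$ic50_uM <- 1e5   # essentially no activity at screen doses
  hill$h <- 1
  truth <- truth_params(drugs, c("ca", "no"), hill, noise_sd = 3)
  specs <- tibble::tibble(drug = drugs, cud_uM = 10, screen_dose_uM = 5)
  res <- quiet(tgmo_run(make_measure_fn(truth), specs, cancer_lines = "ca",
                        normal_line = "no", seed = 1))
  expect_equal(nrow(res$odcs), 0)
  expect_equal(res$status, "failed")
  expect_equal(res$reason, "no beneficial terms")
})

test_that("search output serialises to the JSON artefacts", {
  truth <- make_rcc_scenario()
  res <- quiet(tgmo_run(make_measure_fn(truth), rcc_drug_table(),
                        cancer_lines = "786O", normal_line = "RPTEC",
                        seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_search_json(res, dir)
  odc <- jsonlite::read_json(file.path(dir, "odc.json"))
  expect_gt(length(odc), 0)
  tr <- jsonlite::read_json(file.path(dir, "search_trace.json"))
  expect_equal(tr$status, "converged")
})
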