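test_that("the Bliss generator reproduces its closed-form expectations", {
  truth <- toy_truth(0.8, 0.8, psi12 = 0, noise_sd = 0)
  conc <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b")))
  sim <- simulate_bliss(truth, conc, "cell", replicates = 1, seed = 1)
  expect_equal(sim$viability_pct[1], 100)         # vehicle identity
  expect_equal(sim$viability_pct[2], 64)          # 0.8 * 0.8
  syn <- toy_truth(0.8, 0.8, psi12 = -2, noise_sd = 0)
  sim_syn <- simulate_bliss(syn, conc, "cell", replicates = 1, seed = 1)
  expect_lt(sim_syn$viability_pct[2], 64)         # synergy lowers viability
  expect_equal(sim_syn$viability_pct[2], 64 * exp(-2 * 0.04))
  ant <- toy_truth(0.8, 0.8, psi12 = 2, noise_sd = 0)
  expect_gt(simulate_bliss(ant, conc, "cell", 1, 1)$viability_pct[2], 64)
})

test_that("seeded simulations are reproducible and truncated at zero", {
  truth <- toy_truth(0.5, 0.5, noise_sd = 40)
  conc <- matrix(c(3, 3), 1, 2, dimnames = list(NULL, c("a", "b")))
  s1 <- simulate_bliss(truth, conc, "cell", replicates = 200, seed = 99)
  s2 <- simulate_bliss(truth, conc, "cell", replicates = 200, seed = 99)
  expect_identical(s1, s2)
  expect_true(all(s1$viability_pct >= 0))
  expect_false(identical(
    s1, simulate_bliss(truth, conc, "cell", replicates = 200, seed = 100)))
})

test_that("raising a dose never raises expected viability without antagonism", {
  truth <- toy_truth(0.7, 0.9, psi12 = -1, noise_sd = 0)
  doses <- seq(0, 5, by = 0.25)
  conc <- cbind(a = doses, b = 1)
  v <- simulate_bliss(truth, conc, "cell", replicates = 1, seed = 1)
  expect_true(all(diff(v$viability_pct) <= 1e-12))
})

test_that("unknown drugs and malformed truths are rejected", {
  truth <- toy_truth()
  conc <- matrix(1, 1, 1, dimnames = list(NULL, "zzz"))
  expect_error(simulate_bliss(truth, conc, "cell"),
               class = "tgmo_validation_error")
  hill <- tibble::tibble(drug = c("a", "b"), cell_line = "cell",
                         ic50_uM = 1, h = 1)
  asym <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(truth_params(c("a", "b"), "cell", hill,
                            psi = list(cell = asym)),
               class = "tgmo_validation_error")
  expect_error(truth_params(c("a", "b"), "cell", hill, noise_sd = -1),
               class = "tgmo_validation_error")
})

test_that("the linear-truth generator feeds back the exact model family", {
  d <- generate_oacd(4, seed = 2)
  drugs <- attr(d, "drug_order")
  truth <- truth_params(drugs, "cell",
                        tibble::tibble(drug = drugs, cell_line = "cell",
                                       ic50_uM = 1, h = 1),
                        noise_sd = 0,
                        linear_beta = c(`(Intercept)` = 100))
  sim <- simulate_linear(truth, d, replicates = 2, seed = 1)
  expect_true(all(sim$y == 100))
  bad <- truth_params(drugs, "cell",
                      tibble::tibble(drug = drugs, cell_line = "cell",
                                     ic50_uM = 1, h = 1),
                      noise_sd = 0, linear_beta = c(nosuch = 1))
  expect_error(simulate_linear(bad, d), class = "tgmo_validation_error")
})

test_that("the scripted scenario encodes the planted roles", {
  truth <- make_rcc_scenario()
  expect_s3_class(truth, "tgmo_truth")
  expect_identical(truth, make_rcc_scenario())  # deterministic
  doses <- setNames(rcc_drug_table()$screen_dose_uM, rcc_drug_table()$drug)
  trio <- c("aspirin", "axitinib", "osimertinib")
  for (ln in c("786O", "UOK276")) {
    P <- truth$psi[[ln]]
    # round-one trio: mutually antagonistic
    expect_true(all(P[trio, trio][upper.tri(P[trio, trio])] > 0))
    # surviving synergy pair, planted in both cancer lines
    expect_lt(P["crizotinib", "telaglenastat"], 0)
  }
  expect_true(all(truth$psi[["RPTEC"]] == 0))
  # the trio is toxic alone at its screening dose on the normal line
  hp <- truth$hill[truth$hill$cell_line == "RPTEC", ]
  v_normal <- vapply(trio, function(dd) {
    r <- hp[hp$drug == dd, ]
    100 / (1 + (doses[dd] / r$ic50_uM)^r$h)
  }, numeric(1))
  expect_true(all(flag_toxicity(v_normal)))
})
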