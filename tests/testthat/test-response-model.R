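test_that("therapeutic window is the healthy-minus-cancer difference", {
  expect_equal(compute_tw(79.1, 73.2), 5.9)
  expect_equal(compute_tw(77.2, 63.7), 13.5)
  expect_equal(compute_tw(64, 64), 0)
  # antisymmetry under swapping the lines
  a <- withr::with_seed(5, runif(20, 40, 100))
  b <- withr::with_seed(6, runif(20, 40, 100))
  expect_equal(compute_tw(a, b), -compute_tw(b, a))
})

test_that("the second-order model matrix has the documented shape", {
  for (k in c(4, 10)) {
    d <- generate_oacd(k, seed = 1)
    X <- build_model_matrix(d)
    expect_equal(ncol(X), 1 + 2 * k + k * (k - 1) / 2)
    expect_equal(nrow(X), nrow(d))
    # every non-intercept column is centered
    expect_true(all(abs(colMeans(X[, -1])) < 1e-12))
  }
  d <- generate_oacd(3, seed = 1)
  X3 <- build_model_matrix(d, replicates = 3)
  expect_equal(nrow(X3), 3 * nrow(d))
})

test_that("forced fits equal the normal-equations OLS solution", {
  d <- generate_oacd(4, seed = 2)
  X <- build_model_matrix(d, replicates = 2)
  y <- withr::with_seed(8, 100 - 3 * X[, 2] + rnorm(nrow(X), 0, 4))
  m <- stepwise_fit(X, y, selection = "forced")
  beta_ref <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(m$terms$beta), unname(drop(beta_ref)), tolerance = 1e-8)
})

test_that("noiseless planted coefficients are recovered exactly by stepwise", {
  d <- generate_oacd(3, seed = 4)
  truth <- truth_params(attr(d, "drug_order"), "cell",
                        hill = tibble::tibble(drug = attr(d, "drug_order"),
                                              cell_line = "cell",
                                              ic50_uM = 1, h = 1),
                        noise_sd = 0,
                        linear_beta = c(`(Intercept)` = 100,
                                       drug01 = -10,
                                       `drug01:drug02` = -8))
  sim <- simulate_linear(truth, d, replicates = 3, seed = 1)
  X <- build_model_matrix(d, replicates = 3)
  y <- align_endpoint(d, sim, value = "y")
  m <- stepwise_fit(X, y)
  expect_setequal(m$terms$label[-1], c("drug01", "drug01:drug02"))
  got <- setNames(m$terms$beta, m$terms$label)
  expect_equal(got[["(Intercept)"]], 100, tolerance = 1e-8)
  expect_equal(got[["drug01"]], -10, tolerance = 1e-8)
  expect_equal(got[["drug01:drug02"]], -8, tolerance = 1e-8)
})

test_that("a constant response yields the intercept-only model with warning", {
  d <- generate_oacd(3, seed = 4)
  X <- build_model_matrix(d)
  expect_warning(m <- stepwise_fit(X, rep(100, nrow(X))), "intercept-only")
  expect_equal(nrow(m$terms), 1)
})

test_that("stepwise agrees with the base-R add1/drop1 oracle", {
  d <- generate_oacd(2, seed = 3)  # 5 candidate terms
  X <- build_model_matrix(d, replicates = 2)
  for (s in 1:8) {
    y <- withr::with_seed(s, 90 - 6 * X[, 2] + 4 * X[, 6] +
                            rnorm(nrow(X), 0, 5))
    m <- quiet(stepwise_fit(X, y))
    o <- oracle_stepwise(X, y)
    expect_setequal(m$terms$label[-1], o$selected)
    expect_equal(sort(unname(m$terms$beta)), sort(unname(o$coef)),
                 tolerance = 1e-8)
  }
})

test_that("Cook's distances match explicit leave-one-out refits", {
  set.seed(21)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(12), x2 = rnorm(12))
  attr(X, "terms") <- tibble::tibble(label = colnames(X),
                                     kind = c("intercept", "linear", "linear"),
                                     i = c(NA, 1L, 2L), j = NA_integer_)
  y <- 5 + 2 * X[, 2] + rnorm(12)
  m <- stepwise_fit(X, y, selection = "forced")
  expect_lt(max(abs(cooks_distances(m) - oracle_cooks(X, y))), 1e-10)
})

test_that("the influence filter removes a planted outlier and refits once", {
  d <- generate_oacd(3, seed = 6)
  X <- build_model_matrix(d, replicates = 2)
  y <- withr::with_seed(13, 100 - 5 * X[, 2] + rnorm(nrow(X), 0, 2))
  y[17] <- y[17] + 50
  m <- quiet(stepwise_fit(X, y))
  f <- cooks_filter(m)
  expect_true(17 %in% f$removed_points$row)
  expect_false(17 %in% f$kept_rows)
  # clean data: the single-pass rule trims only a small tail of rows
  frac_removed <- vapply(1:60, function(s) {
    yy <- withr::with_seed(100 + s, 100 - 5 * X[, 2] + rnorm(nrow(X), 0, 2))
    nrow(cooks_filter(quiet(stepwise_fit(X, yy)))$removed_points) / nrow(X)
  }, numeric(1))
  expect_lt(mean(frac_removed), 0.12)
})

test_that("diagnostics report exact fits and the fitted-observed identity", {
  d <- generate_oacd(3, seed = 7)
  X <- build_model_matrix(d, replicates = 2)
  y_exact <- 80 - 4 * X[, 2] + 2 * X[, 3]
  m <- quiet(stepwise_fit(X, y_exact))
  g <- glance(m)
  expect_equal(g$r2, 1, tolerance = 1e-12)
  expect_equal(g$rmse, 0, tolerance = 1e-9)
  # r(fitted, observed)^2 equals R^2 for any OLS fit with intercept
  y <- withr::with_seed(31, y_exact + rnorm(length(y_exact), 0, 6))
  m2 <- stepwise_fit(X, y, selection = "forced")
  g2 <- glance(m2)
  expect_equal(g2$fitted_observed_r^2, g2$r2, tolerance = 1e-10)
})

test_that("coefficient bias shrinks as plate noise vanishes", {
  d <- generate_oacd(3, seed = 9)
  X <- build_model_matrix(d, replicates = 3)
  target <- c(`(Intercept)` = 100, drug02 = -7)
  bias <- vapply(c(5, 2, 0.5, 0), function(sig) {
    est <- vapply(1:25, function(s) {
      y <- withr::with_seed(s * 7 + round(sig * 1000),
                           100 - 7 * X[, 3] + rnorm(nrow(X), 0, sig))
      m <- quiet(stepwise_fit(X, y))
      b <- m$terms$beta[m$terms$label == "drug02"]
      if (length(b) == 0) NA_real_ else b
    }, numeric(1))
    abs(mean(est, na.rm = TRUE) + 7)
  }, numeric(1))
  expect_lt(bias[4], 1e-10)
  expect_lt(bias[3], bias[1] + 0.2)
})
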