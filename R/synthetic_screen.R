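# Synthetic combination-screen generator. Monotherapy responses follow Hill
# inhibition curves; combinations follow Bliss independence modulated by
# planted pairwise interactions; plate noise is additive Gaussian on the
# percent scale, truncated at zero.

#' Construct simulator ground truth
#'
#' @param drugs Character vector of drug names.
#' @param lines Character vector of cell-line names.
#' @param hill Tibble with columns `drug`, `cell_line`, `ic50_uM`, `h`
#'   covering every drug/line pair.
#' @param psi Named list, one symmetric zero-diagonal k x k matrix per cell
#'   line: log-scale pairwise interaction modifiers (negative = synergy,
#'   positive = antagonism). Missing lines default to zero matrices.
#' @param noise_sd Plate noise standard deviation in viability points
#'   (default 5).
#' @param linear_beta Optional named coefficient vector for the
#'   regression-family generator [simulate_linear()]; names must match
#'   model-matrix column labels.
#'
#' @return A `tgmo_truth` object.
#' @export
truth_params <- function(drugs, lines, hill, psi = NULL, noise_sd = 5,
                         linear_beta = NULL) {
  k <- length(drugs)
  if (noise_sd < 0) abort("noise_sd must be >= 0.",
                          class = "tgmo_validation_error")
  need <- tidyr::expand_grid(drug = drugs, cell_line = lines)
  got <- dplyr::semi_join(need, hill, by = c("drug", "cell_line"))
  if (nrow(got) < nrow(need)) {
    abort("Hill parameters missing for some drug/line pairs.",
          class = "tgmo_validation_error")
  }
  if (any(hill$ic50_uM <= 0) || any(hill$h <= 0)) {
    abort("Hill parameters must satisfy ic50 > 0 and h > 0.",
          class = "tgmo_validation_error")
  }
  psi <- psi %||% list()
  for (ln in lines) {
    if (is.null(psi[[ln]])) {
      psi[[ln]] <- matrix(0, k, k, dimnames = list(drugs, drugs))
    } else {
      m <- psi[[ln]][drugs, drugs]
      if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0)) {
        abort("Each interaction matrix must be symmetric with zero diagonal.",
              class = "tgmo_validation_error")
      }
      psi[[ln]] <- m
    }
  }
  structure(list(drugs = drugs, lines = lines, hill = hill, psi = psi,
                 noise_sd = noise_sd, linear_beta = linear_beta),
            class = "tgmo_truth")
}

#' @export
print.tgmo_truth <- function(x, ...) {
  cat("<tgmo_truth>", length(x$drugs), "drugs x", length(x$lines),
      "lines, noise sd =", x$noise_sd, "\n")
  invisible(x)
}

# expected viability fraction of one line for a run x drug concentration
# matrix: Bliss product of monotherapy survivals times
# exp(sum_{i<j} psi_ij * a_i * a_j) with a_i the monotherapy inhibited
# fraction at the run's dose.
expected_fraction <- function(truth, conc, cell_line) {
  drugs <- colnames(conc)
  unknown <- setdiff(drugs, truth$drugs)
  if (length(unknown) > 0) {
    abort(paste0("Truth lacks drug(s): ", paste(unknown, collapse = ", ")),
          class = "tgmo_validation_error")
  }
  hp <- truth$hill[truth$hill$cell_line == cell_line, ]
  V <- vapply(drugs, function(d) {
    r <- hp[hp$drug == d, ]
    1 / (1 + (conc[, d] / r$ic50_uM)^r$h)
  }, numeric(nrow(conc)))
  V <- matrix(V, nrow = nrow(conc), dimnames = list(NULL, drugs))
  A <- 1 - V
  base <- apply(V, 1, prod)
  P <- truth$psi[[cell_line]][drugs, drugs, drop = FALSE]
  inter <- 0.5 * rowSums((A %*% P) * A)  # sum_{i<j} psi_ij a_i a_j
  base * exp(inter)
}

#' Simulate a combination screen under Bliss independence
#'
#' Expected viability of each run is the product of the monotherapy
#' survival fractions (Bliss independence), multiplied by
#' `exp(sum psi_ij a_i a_j)` where `a_i` is the inhibited fraction of drug i
#' at its run dose — so negative `psi` lowers combination viability
#' (synergy) and positive `psi` raises it (antagonism). Reported values are
#' `100 * fraction` plus Gaussian plate noise, truncated at 0 (values above
#' 100 are possible, as with ATP readouts).
#'
#' @param truth A `tgmo_truth`.
#' @param conc Concentration table from [map_to_concentrations()] (`run_id`
#'   plus one µM column per drug), or a plain matrix with drug columns.
#' @param cell_line Cell line to simulate.
#' @param replicates Number of replicates (default 3).
#' @param seed Integer seed.
#'
#' @return Tibble of viability records: `run_id`, `cell_line`, `replicate`,
#'   `viability_pct`.
#' @export
simulate_bliss <- function(truth, conc, cell_line, replicates = 3, seed = 1L) {
  if (replicates < 1) abort("replicates must be >= 1.",
                            class = "tgmo_validation_error")
  if (is.data.frame(conc)) {
    run_id <- conc$run_id %||% sprintf("R%03d", seq_len(nrow(conc)))
    M <- as.matrix(conc[, setdiff(names(conc), "run_id"), drop = FALSE])
  } else {
    run_id <- rownames(conc) %||% sprintf("R%03d", seq_len(nrow(conc)))
    M <- conc
  }
  mu <- 100 * expected_fraction(truth, M, cell_line)
  out <- tidyr::expand_grid(run_id = run_id, replicate = seq_len(replicates))
  out <- dplyr::arrange(out, match(.data$run_id, run_id), .data$replicate)
  mu_rep <- rep(mu, each = replicates)
  noise <- if (truth$noise_sd > 0) {
    withr::with_seed(as.integer(seed),
                     rnorm(nrow(out), 0, truth$noise_sd))
  } else {
    rep(0, nrow(out))
  }
  tibble::tibble(run_id = out$run_id, cell_line = cell_line,
                 replicate = out$replicate,
                 viability_pct = pmax(mu_rep + noise, 0))
}

#' Simulate endpoint values from an explicit linear truth
#'
#' Generates `y = X beta + noise` on the centered second-order model matrix
#' of a design — the generator whose family matches the fitted model
#' exactly, used for identifiability and power checks.
#'
#' @param truth A `tgmo_truth` with `linear_beta` set (named coefficients;
#'   names must match model-matrix column labels, e.g. `"drug01"`,
#'   `"drug01:drug02"`, `"drug01^2"`, `"(Intercept)"`).
#' @param design A `tgmo_design`.
#' @param replicates Replicates per run.
#' @param seed Integer seed.
#'
#' @return Tibble: `run_id`, `replicate`, `y`.
#' @export
simulate_linear <- function(truth, design, replicates = 3, seed = 1L) {
  beta <- truth$linear_beta
  if (is.null(beta)) {
    abort("truth has no linear_beta.", class = "tgmo_validation_error")
  }
  X <- build_model_matrix(design, replicates = replicates)
  bad <- setdiff(names(beta), colnames(X))
  if (length(bad) > 0) {
    abort(paste0("linear_beta references unknown term(s): ",
                 paste(bad, collapse = ", ")),
          class = "tgmo_validation_error")
  }
  b <- setNames(rep(0, ncol(X)), colnames(X))
  b[names(beta)] <- beta
  mu <- drop(X %*% b)
  noise <- if (truth$noise_sd > 0) {
    withr::with_seed(as.integer(seed), rnorm(length(mu), 0, truth$noise_sd))
  } else {
    rep(0, length(mu))
  }
  tibble::tibble(run_id = attr(X, "run_id"),
                 replicate = attr(X, "replicate"),
                 y = mu + noise)
}

#' Measurement closure over a simulator truth
#'
#' Adapts a `tgmo_truth` to the measurement interface of [tgmo_run()]: a
#' function of (concentration table, cell line, replicates, seed) returning
#' viability records.
#'
#' @param truth A `tgmo_truth`.
#' @return A function usable as the `measure` argument of [tgmo_run()].
#' @export
make_measure_fn <- function(truth) {
  force(truth)
  function(conc, cell_line, replicates, seed) {
    simulate_bliss(truth, conc, cell_line, replicates = replicates,
                   seed = seed)
  }
}

#' Ten-drug renal-carcinoma screening panel
#'
#' The drug panel used throughout the package examples: ten approved or
#' clinical-stage agents with their clinically used doses (CUD, µM, derived
#' from plasma exposure) and the level-2 screening doses after IC20/CUD
#' capping (osimertinib at its reduced dose).
#'
#' @return Tibble: `drug`, `cud_uM`, `screen_dose_uM`.
#' @export
rcc_drug_table <- function() {
  tibble::tribble(
    ~drug,           ~cud_uM, ~screen_dose_uM,
    "aspirin",        80.000,          40.000,
    "axitinib",        0.029,           0.0145,
    "crizotinib",      0.664,           0.664,
    "osimertinib",     0.469,           0.059,
    "palbociclib",     0.264,           0.132,
    "selumetinib",     0.296,           0.148,
    "simvastatin",     0.005,           0.0025,
    "telaglenastat",   2.113,           0.0065,
    "U-104",           9.524,           4.762,
    "vismodegib",     17.000,           6.377
  )
}

#' Final optimized drug combinations of the worked example
#'
#' The three combinations the worked search converges to: the four-drug
#' combination, the synergistic pair, and the purely additive triple, with
#' their final doses in µM.
#'
#' @return Tibble: `odc`, `drug`, `dose_uM`.
#' @export
rcc_odc_table <- function() {
  tibble::tribble(
    ~odc,    ~drug,           ~dose_uM,
    "ODC_A", "crizotinib",       0.664,
    "ODC_A", "telaglenastat",    0.013,
    "ODC_A", "U-104",            9.524,
    "ODC_A", "vismodegib",      12.754,
    "ODC_B", "telaglenastat",    0.013,
    "ODC_B", "U-104",            9.524,
    "ODC_B", "vismodegib",      12.754,
    "ODC_C", "crizotinib",       0.664,
    "ODC_C", "telaglenastat",    0.013
  )
}

# IC50 for a target viability fraction v at dose d with slope h:
# v = 1/(1+(d/ic50)^h)  =>  ic50 = d * (v/(1-v))^(1/h)
ic50_for_target <- function(dose, v, h) {
  dose * (v / (1 - v))^(1 / h)
}

#' Scripted ten-drug screen scenario
#'
#' Ground truth for the end-to-end worked example: ten drugs, two cancer
#' lines (786O-like and UOK276-like) plus one non-malignant line
#' (RPTEC-like). Three drugs are planted detrimental in round one (two
#' mutually antagonistic weak drugs and one drug toxic to the normal line),
#' three more carry antagonisms that surface in round two, and the
#' survivors include one synergistic pair (a MET-inhibitor-like and a
#' GLS1-inhibitor-like drug) alongside two additively beneficial drugs.
#'
#' @param noise_sd Plate noise (viability points, default 5).
#' @return A `tgmo_truth`.
#' @export
make_rcc_scenario <- function(noise_sd = 5) {
  drugs <- rcc_drug_table()$drug
  doses <- setNames(rcc_drug_table()$screen_dose_uM, drugs)
  cancer_lines <- c("786O", "UOK276")
  lines <- c(cancer_lines, "RPTEC")

  # monotherapy viability fractions at the level-2 screening dose; mild
  # single-agent effects keep the Bliss product surface close to additive
  # so that only the planted interactions rise above significance
  v_cancer <- c(aspirin = 0.90, axitinib = 0.89, crizotinib = 0.90,
                osimertinib = 0.91, palbociclib = 0.93, selumetinib = 0.91,
                simvastatin = 0.92, telaglenastat = 0.88, `U-104` = 0.92,
                vismodegib = 0.91)
  # the round-one trio is frankly toxic to the non-malignant line
  v_normal <- c(aspirin = 0.75, axitinib = 0.74, crizotinib = 0.97,
                osimertinib = 0.72, palbociclib = 0.98, selumetinib = 0.98,
                simvastatin = 0.99, telaglenastat = 0.97, `U-104` = 0.98,
                vismodegib = 0.98)
  h_cancer <- 1.0
  h_normal <- 1.0

  hill <- dplyr::bind_rows(
    purrr::map_dfr(cancer_lines, function(ln) {
      tibble::tibble(drug = drugs, cell_line = ln,
                     ic50_uM = ic50_for_target(doses[drugs],
                                               v_cancer[drugs], h_cancer),
                     h = h_cancer)
    }),
    tibble::tibble(drug = drugs, cell_line = "RPTEC",
                   ic50_uM = ic50_for_target(doses[drugs],
                                             v_normal[drugs], h_normal),
                   h = h_normal)
  )

  psi_cancer <- matrix(0, 10, 10, dimnames = list(drugs, drugs))
  set_psi <- function(m, a, b, val) {
    m[a, b] <- val; m[b, a] <- val; m
  }
  # round-one detrimental trio: antagonistic triangle (all three also toxic)
  psi_cancer <- set_psi(psi_cancer, "aspirin", "axitinib", 18)
  psi_cancer <- set_psi(psi_cancer, "aspirin", "osimertinib", 18)
  psi_cancer <- set_psi(psi_cancer, "axitinib", "osimertinib", 18)
  # round-two antagonistic triangle among the middle trio
  psi_cancer <- set_psi(psi_cancer, "simvastatin", "selumetinib", 18)
  psi_cancer <- set_psi(psi_cancer, "selumetinib", "palbociclib", 18)
  psi_cancer <- set_psi(psi_cancer, "simvastatin", "palbociclib", 18)
  # the surviving quartet is additive on the percent-of-control scale:
  # under Bliss independence the product surface itself curves upward by
  # ~a_i*a_j, so percent-scale additivity corresponds to a small negative
  # psi (~ -1/(v_i*v_j)) rather than zero
  additive_quartet <- c("crizotinib", "telaglenastat", "U-104", "vismodegib")
  for (a in additive_quartet) for (b in additive_quartet) {
    if (a < b) psi_cancer <- set_psi(psi_cancer, a, b, -8)
  }
  # surviving synergy: MET-inhibitor-like x GLS1-inhibitor-like
  psi_cancer <- set_psi(psi_cancer, "crizotinib", "telaglenastat", -26)

  psi <- list(`786O` = psi_cancer, UOK276 = psi_cancer,
              RPTEC = matrix(0, 10, 10, dimnames = list(drugs, drugs)))

  truth_params(drugs, lines, hill, psi = psi, noise_sd = noise_sd)
}
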