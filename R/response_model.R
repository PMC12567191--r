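# Second-order response-surface regression on screen endpoints: centered
# full-quadratic model matrix, p-value-driven bidirectional stepwise
# selection, Cook's-distance outlier handling, and the usual fit diagnostics.

#' Therapeutic window of a condition
#'
#' Selectivity statistic of one screen condition: viability of the
#' non-malignant line minus viability of the cancer line, in percentage
#' points. Positive values mean the condition hits the cancer cells harder
#' than the healthy cells.
#'
#' @param viability_normal Normal-line viability (% of control).
#' @param viability_cancer Cancer-line viability (% of control).
#'
#' @return Numeric vector of therapeutic-window values (percentage points).
#' @export
#' @examples
#' compute_tw(79.1, 73.2)  # 5.9
#' compute_tw(77.2, 63.7)  # 13.5
compute_tw <- function(viability_normal, viability_cancer) {
  viability_normal - viability_cancer
}

# Build the centered second-order model matrix from a coded-level matrix.
# Columns: intercept, centered x_i, centered (centered x_i)^2, centered
# products of centered mains, for i < j in the design's drug order.
model_matrix_from_levels <- function(L, quadratic = TRUE) {
  k <- ncol(L)
  drugs <- colnames(L)
  ctr <- function(z) z - mean(z)
  Lc <- apply(L, 2, ctr)
  if (k == 1) Lc <- matrix(Lc, ncol = 1, dimnames = list(NULL, drugs))

  cols <- list(`(Intercept)` = rep(1, nrow(L)))
  terms <- tibble::tibble(label = "(Intercept)", kind = "intercept",
                          i = NA_integer_, j = NA_integer_)
  for (i in seq_len(k)) {
    cols[[drugs[i]]] <- Lc[, i]
    terms <- dplyr::add_row(terms, label = drugs[i], kind = "linear",
                            i = i, j = NA_integer_)
  }
  if (quadratic) {
    for (i in seq_len(k)) {
      lab <- paste0(drugs[i], "^2")
      cols[[lab]] <- ctr(Lc[, i]^2)
      terms <- dplyr::add_row(terms, label = lab, kind = "quadratic",
                              i = i, j = NA_integer_)
    }
    if (k >= 2) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        lab <- paste0(drugs[i], ":", drugs[j])
        cols[[lab]] <- ctr(Lc[, i] * Lc[, j])
        terms <- dplyr::add_row(terms, label = lab, kind = "interaction",
                                i = i, j = j)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "terms") <- terms
  attr(X, "drug_order") <- drugs
  X
}

#' Build the second-order model matrix of a design
#'
#' Predictors are the coded levels centered per column; quadratic columns
#' are squares of the centered mains (re-centered) and interaction columns
#' their pairwise products (re-centered). The column count for k drugs is
#' `1 + 2k + k(k-1)/2`. Rows are repeated per replicate so replicate-level
#' responses enter the fit individually.
#'
#' @param design A `tgmo_design`.
#' @param replicates Number of replicate rows per run (default 1).
#'
#' @return Numeric model matrix with a `terms` attribute describing each
#'   column (`kind`: intercept, linear, quadratic, interaction; drug
#'   indices `i`, `j`).
#' @export
build_model_matrix <- function(design, replicates = 1) {
  L <- design_levels(design)
  X <- model_matrix_from_levels(L, quadratic = TRUE)
  if (replicates > 1) {
    idx <- rep(seq_len(nrow(X)), each = replicates)
    terms <- attr(X, "terms")
    drugs <- attr(X, "drug_order")
    X <- X[idx, , drop = FALSE]
    attr(X, "terms") <- terms
    attr(X, "drug_order") <- drugs
  }
  attr(X, "run_id") <- rep(design$run_id, each = replicates)
  attr(X, "replicate") <- rep(seq_len(replicates), times = nrow(design))
  X
}

#' Align replicate-level endpoint values with a model matrix
#'
#' Orders a record tibble to match the row layout of [build_model_matrix()]
#' (design run order, replicates nested within run).
#'
#' @param design A `tgmo_design`.
#' @param data Tibble with `run_id`, `replicate` and the endpoint column.
#' @param value Name of the endpoint column.
#' @param replicates Expected replicate count per run.
#'
#' @return Numeric vector aligned 1:1 with the model-matrix rows.
#' @export
align_endpoint <- function(design, data, value = "viability_pct",
                           replicates = NULL) {
  counts <- dplyr::count(data, .data$run_id)
  if (is.null(replicates)) replicates <- max(counts$n)
  if (!all(counts$n == replicates) ||
      !setequal(counts$run_id, design$run_id)) {
    abort("Endpoint records do not align 1:1 with design runs x replicates.",
          class = "tgmo_validation_error")
  }
  d <- dplyr::arrange(data,
                      match(.data$run_id, design$run_id),
                      .data$replicate)
  d[[value]]
}

ols_fit <- function(X, y, included) {
  Xs <- X[, included, drop = FALSE]
  n <- nrow(Xs)
  p <- ncol(Xs)
  qx <- qr(Xs)
  if (qx$rank < p) {
    abort("Rank-deficient term set in OLS refit.", class = "tgmo_fit_error")
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(Xs %*% beta)
  resid <- y - fitted
  df_res <- n - p
  sse <- sum(resid^2)
  s2 <- if (df_res > 0) sse / df_res else NA_real_
  xtx_inv <- chol2inv(chol(crossprod(Xs)))
  se <- if (df_res > 0) sqrt(diag(xtx_inv) * s2) else rep(NA_real_, p)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  list(beta = beta, se = se, p_value = pval, fitted = fitted, resid = resid,
       sse = sse, df_res = df_res, qx = qx, n = n, p = p)
}

#' Bidirectional stepwise fit of a second-order model
#'
#' Starting from the intercept-only model, terms are entered one at a time
#' by the smallest partial-F p-value below `p_enter`; after each entry,
#' included terms whose p-value has risen above `p_remove` are dropped
#' (worst first). Every step refits by ordinary least squares. Candidates
#' that are numerically collinear with the current model are skipped and
#' recorded. Term hierarchy is not enforced: an interaction may stay without
#' its main effects.
#'
#' @param X Model matrix from [build_model_matrix()].
#' @param y Endpoint vector aligned with the rows of `X`.
#' @param endpoint Endpoint label, `"cancer_viability"` or
#'   `"therapeutic_window"`.
#' @param p_enter Entry threshold on the candidate p-value (default 0.05).
#' @param p_remove Removal threshold on included-term p-values (default
#'   0.10).
#' @param selection `"stepwise"` (default) or `"forced"` to fit the full
#'   term set without selection.
#' @param max_steps Safety cap on selection steps.
#'
#' @return A `tgmo_model`: term table with coefficients, standard errors and
#'   p-values, fit diagnostics, and the data needed for outlier filtering.
#' @export
stepwise_fit <- function(X, y, endpoint = "cancer_viability",
                         p_enter = 0.05, p_remove = 0.10,
                         selection = c("stepwise", "forced"),
                         max_steps = 500) {
  selection <- match.arg(selection)
  terms <- attr(X, "terms")
  n <- nrow(X)
  if (length(y) != n) {
    abort("length(y) must equal nrow(X).", class = "tgmo_validation_error")
  }

  skipped <- character(0)
  if (selection == "forced") {
    included <- seq_len(ncol(X))
  } else {
    included <- 1L  # intercept
    for (step in seq_len(max_steps)) {
      changed <- FALSE
      candidates <- setdiff(seq_len(ncol(X)), included)
      df_new <- n - length(included) - 1
      sse_floor <- 1e-16 * (sum(y^2) + 1)  # numerically exact fit: stop entering
      if (length(candidates) > 0 && df_new > 0) {
        qx <- qr(X[, included, drop = FALSE])
        res <- qr.resid(qx, y)
        sse <- sum(res^2)
        if (sse < sse_floor) break
        Z <- X[, candidates, drop = FALSE]
        Zp <- Z - qr.fitted(qx, Z)
        d <- colSums(Zp^2)
        scale_ref <- colSums(Z^2)
        collinear <- d <= 1e-10 * pmax(scale_ref, 1)
        rn <- colSums(Zp * res)
        sse_new <- pmax(sse - ifelse(collinear, 0, rn^2 / d), 0)
        fstat <- ifelse(collinear | sse_new <= 0,
                        ifelse(collinear, 0, Inf),
                        (sse - sse_new) / (sse_new / df_new))
        pvals <- ifelse(collinear, 1, pf(fstat, 1, df_new, lower.tail = FALSE))
        newly_skipped <- colnames(Z)[collinear & !(colnames(Z) %in% skipped)]
        if (length(newly_skipped) > 0) {
          skipped <- c(skipped, newly_skipped)
          inform(paste0("Skipping collinear candidate term(s): ",
                        paste(newly_skipped, collapse = ", ")))
        }
        best <- which.min(pvals)
        if (pvals[best] < p_enter) {
          included <- c(included, candidates[best])
          changed <- TRUE
        }
      }
      # backward pass: drop worst included term while above p_remove
      repeat {
        if (length(included) <= 1) break
        f <- ols_fit(X, y, included)
        pv <- f$p_value
        pv[1] <- 0  # intercept never leaves
        worst <- which.max(pv)
        if (is.finite(pv[worst]) && pv[worst] > p_remove) {
          included <- included[-worst]
          changed <- TRUE
        } else break
      }
      if (!changed) break
    }
    if (length(included) == 1) {
      warn("No term met the entry criterion; returning intercept-only model.")
    }
  }

  fit <- ols_fit(X, y, included)
  new_tgmo_model(X, y, included, fit, terms, endpoint,
                 p_enter = p_enter, p_remove = p_remove,
                 selection = selection, skipped = skipped)
}

new_tgmo_model <- function(X, y, included, fit, terms, endpoint,
                           p_enter, p_remove, selection, skipped,
                           removed_points = NULL, kept_rows = NULL) {
  tt <- terms[included, ]
  tt$beta <- unname(fit$beta)
  tt$se <- unname(fit$se)
  tt$p_value <- unname(fit$p_value)
  structure(list(
    endpoint = endpoint,
    terms = tt,
    included = included,
    all_terms = terms,
    diagnostics = diagnostics_from_fit(fit, y_used = if (is.null(kept_rows)) y else y[kept_rows]),
    removed_points = removed_points %||%
      tibble::tibble(row = integer(0), cooks_d = numeric(0)),
    kept_rows = kept_rows %||% seq_along(y),
    fitted = fit$fitted,
    residuals = fit$resid,
    skipped = skipped,
    control = list(p_enter = p_enter, p_remove = p_remove,
                   selection = selection),
    X = X, y = y
  ), class = "tgmo_model")
}

diagnostics_from_fit <- function(fit, y_used) {
  n <- fit$n
  p <- fit$p
  sst <- sum((y_used - mean(y_used))^2)
  r2 <- if (sst > 0) 1 - fit$sse / sst else NA_real_
  available <- fit$df_res > 0
  if (!available) {
    warn("Zero residual degrees of freedom: diagnostics unavailable.")
  }
  adj_r2 <- if (available && sst > 0) {
    1 - (1 - r2) * (n - 1) / fit$df_res
  } else NA_real_
  rmse <- if (available) sqrt(fit$sse / fit$df_res) else NA_real_
  anova_p <- if (available && p > 1 && sst > fit$sse) {
    f <- ((sst - fit$sse) / (p - 1)) / (fit$sse / fit$df_res)
    pf(f, p - 1, fit$df_res, lower.tail = FALSE)
  } else if (available && p > 1) {
    1
  } else NA_real_
  r_fo <- if (sd(fit$fitted) > 0) stats::cor(fit$fitted, y_used) else NA_real_
  list(r2 = r2, adj_r2 = adj_r2, rmse = rmse, anova_p = anova_p,
       fitted_observed_r = r_fo, n = n, p = p, df_residual = fit$df_res,
       available = available)
}

#' Cook's distances of a fitted model
#'
#' @param model A `tgmo_model`.
#' @return Numeric vector, one distance per (kept) observation.
#' @export
cooks_distances <- function(model) {
  Xs <- model$X[model$kept_rows, model$included, drop = FALSE]
  y <- model$y[model$kept_rows]
  f <- ols_fit(model$X[model$kept_rows, , drop = FALSE], y, model$included)
  h <- rowSums(qr.Q(f$qx)[, seq_len(f$p), drop = FALSE]^2)
  s2 <- f$sse / f$df_res
  (f$resid^2 * h) / (f$p * s2 * (1 - h)^2)
}

#' Remove influential observations and refit once
#'
#' Computes Cook's distance for every observation of a fitted model,
#' removes those exceeding the cutoff (default: distance above three times
#' the mean distance; alternatively the classic 4/n rule), and refits the
#' same term set by ordinary least squares — a single pass, no iteration.
#' If removal would leave fewer rows than model columns, nothing is removed
#' and the original fit is kept with a warning.
#'
#' @param model A `tgmo_model` from [stepwise_fit()].
#' @param rule `"3x_mean"` (default) or `"4_over_n"`.
#'
#' @return The refitted `tgmo_model` with `removed_points` recording row
#'   indices and distances.
#' @export
cooks_filter <- function(model, rule = c("3x_mean", "4_over_n")) {
  rule <- match.arg(rule)
  n <- length(model$kept_rows)
  p <- length(model$included)
  if (n < p + 2) {
    abort("Too few observations for influence analysis (need >= p + 2).",
          class = "tgmo_validation_error")
  }
  D <- cooks_distances(model)
  cutoff <- if (rule == "3x_mean") 3 * mean(D) else 4 / n
  drop_idx <- which(D > cutoff)
  if (length(drop_idx) == 0) return(model)
  if (n - length(drop_idx) < p) {
    warn("Cook's filtering would leave fewer rows than columns; keeping all.")
    return(model)
  }
  kept <- model$kept_rows[-drop_idx]
  fit <- ols_fit(model$X[kept, , drop = FALSE], model$y[kept], model$included)
  new_tgmo_model(model$X, model$y, model$included, fit, model$all_terms,
                 model$endpoint,
                 p_enter = model$control$p_enter,
                 p_remove = model$control$p_remove,
                 selection = model$control$selection,
                 skipped = model$skipped,
                 removed_points = tibble::tibble(
                   row = model$kept_rows[drop_idx], cooks_d = D[drop_idx]),
                 kept_rows = kept)
}

#' Diagnostics of a fitted model
#'
#' R-squared, adjusted R-squared, residual root-mean-square error, the
#' overall-model ANOVA F-test p-value, and the Pearson correlation between
#' fitted and observed values, all computed on the post-outlier-removal fit.
#'
#' @param model A `tgmo_model`.
#' @return A one-row tibble.
#' @export
model_diagnostics <- function(model) {
  d <- model$diagnostics
  tibble::tibble(endpoint = model$endpoint, r2 = d$r2, adj_r2 = d$adj_r2,
                 rmse = d$rmse, anova_p = d$anova_p,
                 fitted_observed_r = d$fitted_observed_r,
                 n = d$n, df_residual = d$df_residual,
                 n_removed = nrow(model$removed_points))
}

#' Fit one endpoint of a screen round
#'
#' Convenience wrapper: builds the model matrix of the design, aligns the
#' replicate-level endpoint records, runs the stepwise fit and the
#' Cook's-distance pass.
#'
#' @param design A `tgmo_design`.
#' @param data Record tibble (`run_id`, `replicate`, endpoint column).
#' @param endpoint `"cancer_viability"` or `"therapeutic_window"`.
#' @param value Endpoint column name in `data`.
#' @param replicates Replicates per run (inferred when `NULL`).
#' @param cooks Apply the outlier pass (default `TRUE`).
#' @inheritParams stepwise_fit
#' @param cooks_rule Passed to [cooks_filter()].
#'
#' @return A `tgmo_model`.
#' @export
fit_response_model <- function(design, data,
                               endpoint = c("cancer_viability",
                                            "therapeutic_window"),
                               value = "viability_pct", replicates = NULL,
                               p_enter = 0.05, p_remove = 0.10,
                               selection = "stepwise", cooks = TRUE,
                               cooks_rule = "3x_mean") {
  endpoint <- match.arg(endpoint)
  counts <- dplyr::count(data, .data$run_id)
  reps <- replicates %||% max(counts$n)
  X <- build_model_matrix(design, replicates = reps)
  y <- align_endpoint(design, data, value = value, replicates = reps)
  m <- stepwise_fit(X, y, endpoint = endpoint, p_enter = p_enter,
                    p_remove = p_remove, selection = selection)
  if (cooks && length(m$included) > 1) m <- cooks_filter(m, rule = cooks_rule)
  m
}

#' @export
print.tgmo_model <- function(x, ...) {
  cat("<tgmo_model>", x$endpoint, "\n")
  cat("  terms:", nrow(x$terms) - 1, "selected (+ intercept);",
      nrow(x$removed_points), "outlier row(s) removed\n")
  d <- x$diagnostics
  cat(sprintf("  r2 = %.3f, adj r2 = %.3f, rmse = %.3f, anova p = %.3g\n",
              d$r2, d$adj_r2, d$rmse, d$anova_p))
  print(x$terms[, c("label", "kind", "beta", "se", "p_value")])
  invisible(x)
}

#' @method tidy tgmo_model
#' @export
tidy.tgmo_model <- function(x, ...) {
  dplyr::transmute(x$terms,
                   term = .data$label, kind = .data$kind,
                   estimate = .data$beta, std.error = .data$se,
                   p.value = .data$p_value)
}

#' @method glance tgmo_model
#' @export
glance.tgmo_model <- function(x, ...) {
  model_diagnostics(x)
}
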