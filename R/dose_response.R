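#' Evaluate the variable-slope inhibition model
#'
#' The four-parameter logistic with asymptotes fixed at 100 and 0:
#' `v(c) = 100 / (1 + (c / ic50)^h)`. Viability is 50 at `c = ic50` and is
#' strictly decreasing in dose for `h > 0`.
#'
#' @param dose_uM Dose(s), micromolar, non-negative.
#' @param ic50_uM Half-maximal inhibitory concentration (> 0).
#' @param hill_slope Hill slope `h` (> 0).
#'
#' @return Predicted viability in percent of control.
#' @export
hill_viability <- function(dose_uM, ic50_uM, hill_slope) {
  100 / (1 + (dose_uM / ic50_uM)^hill_slope)
}

#' Fit a variable-slope dose-response curve
#'
#' Least-squares fit of the fixed-asymptote logistic
#' `v(c) = 100 / (1 + (c/IC50)^h)` in log10-dose space (the classical
#' "log(inhibitor) vs normalized response, variable slope" model). Curves
#' with no resolvable dose dependence are flagged flat instead of returning
#' meaningless parameters.
#'
#' @param data Tibble with columns `dose_uM` (> 0) and `viability_pct`, or
#'   `NULL` when `doses`/`responses` are given directly.
#' @param doses,responses Alternative vector interface.
#' @param drug,cell_line Labels carried into the result.
#' @param flat_r2 Flatness rule part 1: flag when fit R-squared falls below
#'   this value (default 0.5).
#' @param flat_extrapolation Flatness rule part 2: flag when the fitted IC50
#'   exceeds the maximum tested dose by more than this factor (default 10).
#'
#' @return An object of class `tgmo_curve`: a list with `drug`, `cell_line`,
#'   `ic50_uM`, `hill_slope`, `r2`, `flat_flag` and the fitting data.
#' @export
#' @examples
#' d <- 10^seq(-2, 2, length.out = 8)
#' fit_4pl(doses = d, responses = hill_viability(d, 1, 1))
fit_4pl <- function(data = NULL, doses = NULL, responses = NULL,
                    drug = NA_character_, cell_line = NA_character_,
                    flat_r2 = 0.5, flat_extrapolation = 10) {
  if (!is.null(data)) {
    doses <- data$dose_uM
    responses <- data$viability_pct
  }
  keep <- !is.na(doses) & !is.na(responses) & doses > 0
  doses <- doses[keep]
  responses <- responses[keep]
  if (length(unique(doses)) < 4) {
    abort("At least 4 distinct positive doses are required to fit a curve.",
          class = "tgmo_validation_error")
  }
  lc <- log10(doses)

  out <- list(drug = drug, cell_line = cell_line,
              ic50_uM = NA_real_, hill_slope = NA_real_,
              r2 = NA_real_, flat_flag = FALSE,
              data = tibble::tibble(dose_uM = doses, viability_pct = responses))
  class(out) <- "tgmo_curve"

  sst <- sum((responses - mean(responses))^2)
  if (sst < .Machine$double.eps) {
    # perfectly level response: nothing to fit
    out$flat_flag <- TRUE
    out$r2 <- 0
    return(out)
  }

  # start near the dose where the response crosses 50, if any
  ord <- order(lc)
  start_lic50 <- tryCatch({
    stats::approx(responses[ord], lc[ord], xout = 50, ties = mean)$y
  }, error = function(e) NA_real_)
  if (!is.finite(start_lic50)) start_lic50 <- stats::median(lc)

  # Levenberg-Marquardt on the residual function directly (robust on
  # noiseless data, where the nls model-object machinery can fail); a small
  # ladder of starts guards against local minima
  resid_fn <- function(p) responses - 100 / (1 + 10^(p[2] * (lc - p[1])))
  starts <- list(c(start_lic50, 1), c(start_lic50 + 0.3, 1.7),
                 c(stats::median(lc), 0.7), c(start_lic50 - 0.3, 2.8))
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = c(-6, 0.1), upper = c(6, 10),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) || cand$deviance < fit$deviance)) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    warn(paste0("Dose-response fit did not converge",
                if (!is.na(drug)) paste0(" for ", drug) else "",
                "; curve flagged flat."))
    out$flat_flag <- TRUE
    return(out)
  }

  out$ic50_uM <- 10^fit$par[1]
  out$hill_slope <- fit$par[2]
  out$r2 <- 1 - fit$deviance / sst
  if (out$r2 < flat_r2 || out$ic50_uM > flat_extrapolation * max(doses)) {
    out$flat_flag <- TRUE
  }
  out
}

#' @export
print.tgmo_curve <- function(x, ...) {
  cat("<tgmo_curve>", x$drug, "/", x$cell_line, "\n")
  if (x$flat_flag) {
    cat("  flat curve (no resolvable dose dependence), r2 =",
        format(x$r2, digits = 3), "\n")
  } else {
    cat(sprintf("  IC50 = %.4g uM, Hill slope = %.3g, r2 = %.4f\n",
                x$ic50_uM, x$hill_slope, x$r2))
  }
  invisible(x)
}

#' @method tidy tgmo_curve
#' @export
tidy.tgmo_curve <- function(x, ...) {
  tibble::tibble(drug = x$drug, cell_line = x$cell_line,
                 ic50_uM = x$ic50_uM, hill_slope = x$hill_slope,
                 r2 = x$r2, flat_flag = x$flat_flag)
}

#' Invert a fitted curve to the dose giving f percent inhibition
#'
#' Closed form of the fixed-asymptote logistic:
#' `IC_f = IC50 * (f / (100 - f))^(1/h)`, the concentration at which
#' viability equals `100 - f`.
#'
#' @param curve A `tgmo_curve` (or any list with `ic50_uM`, `hill_slope`,
#'   optionally `flat_flag`).
#' @param f Target percent inhibition, strictly between 0 and 100
#'   (default 20, the IC20 used for screen dosing).
#'
#' @return Concentration in micromolar.
#' @export
#' @examples
#' invert_to_icf(list(ic50_uM = 1, hill_slope = 1), f = 20)  # 0.25
invert_to_icf <- function(curve, f = 20) {
  if (any(f <= 0 | f >= 100)) {
    abort("f must lie strictly between 0 and 100.",
          class = "tgmo_validation_error")
  }
  if (isTRUE(curve$flat_flag)) {
    abort("Curve is flat: no IC can be derived; use the clinically used dose.",
          class = "tgmo_flat_curve_error")
  }
  curve$ic50_uM * (f / (100 - f))^(1 / curve$hill_slope)
}

#' Select the screening dose for one drug
#'
#' Applies the capping rule: when the dose-response curve is flat, or the
#' computed IC20 exceeds the clinically used dose (CUD), the CUD is screened;
#' otherwise the IC20 itself. The returned dose never exceeds the CUD.
#'
#' @param ic20_uM IC20 in micromolar, or `NA` for flat curves.
#' @param cud_uM Clinically used dose (> 0), micromolar.
#' @param flat_flag Logical: was the curve flat?
#'
#' @return Screening dose in micromolar.
#' @export
#' @examples
#' select_screen_dose(5.0, 0.469)             # capped at the CUD
#' select_screen_dose(0.2, 2.113)             # IC20 kept
#' select_screen_dose(NA, 17.0, flat_flag = TRUE)
select_screen_dose <- function(ic20_uM, cud_uM, flat_flag = FALSE) {
  if (any(cud_uM <= 0)) {
    abort("CUD must be positive.", class = "tgmo_validation_error")
  }
  if (any(!flat_flag & is.na(ic20_uM))) {
    abort("Missing IC20 for a non-flat curve.", class = "tgmo_validation_error")
  }
  dplyr::if_else(flat_flag | ic20_uM > cud_uM, cud_uM, ic20_uM)
}

#' Build drug specifications for a screen round
#'
#' Combines chosen level-2 screening doses with the clinically used doses
#' and derives the level-1 (half) doses used by the three-level design.
#'
#' @param drugs Character vector of drug names.
#' @param cud_uM Clinically used doses, micromolar.
#' @param screen_dose_uM Level-2 screening doses, micromolar (each <= CUD).
#'
#' @return A `drug_spec` tibble: `drug`, `cud_uM`, `screen_dose_uM`,
#'   `half_dose_uM`.
#' @export
drug_specs <- function(drugs, cud_uM, screen_dose_uM) {
  if (any(screen_dose_uM > cud_uM + 1e-12)) {
    bad <- drugs[screen_dose_uM > cud_uM + 1e-12]
    abort(paste0("Screen dose exceeds CUD for: ", paste(bad, collapse = ", ")),
          class = "tgmo_validation_error")
  }
  tibble::tibble(drug = drugs, cud_uM = cud_uM,
                 screen_dose_uM = screen_dose_uM,
                 half_dose_uM = screen_dose_uM / 2)
}

#' Plot a fitted dose-response curve
#'
#' @param object A `tgmo_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tgmo_curve
#' @export
autoplot.tgmo_curve <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose_uM,
                                         y = .data$viability_pct)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µM)", y = "viability (% of control)",
                  title = paste(object$drug, object$cell_line, sep = " / "))
  if (!object$flat_flag) {
    grid <- tibble::tibble(
      dose_uM = 10^seq(log10(min(dat$dose_uM)), log10(max(dat$dose_uM)),
                       length.out = 200))
    grid$viability_pct <- hill_viability(grid$dose_uM, object$ic50_uM,
                                         object$hill_slope)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
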