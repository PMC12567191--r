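# Independent oracles used by the regression tests. These deliberately go
# through base R's lm/add1/drop1 machinery rather than the package's own
# QR path.

# p-value-driven bidirectional stepwise selection via lm + F tests
oracle_stepwise <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  labels <- colnames(X)[-1]
  safe <- paste0("t", seq_along(labels))
  dat <- as.data.frame(X[, -1, drop = FALSE])
  names(dat) <- safe
  dat$.y <- y
  in_model <- character(0)
  repeat {
    changed <- FALSE
    form <- stats::reformulate(if (length(in_model)) in_model else "1",
                               response = ".y")
    fit <- stats::lm(form, data = dat)
    out_model <- setdiff(safe, in_model)
    if (length(out_model) > 0) {
      scope <- stats::reformulate(c(in_model, out_model))
      a1 <- stats::add1(fit, scope, test = "F")
      cand <- rownames(a1)[-1]
      pv <- a1[["Pr(>F)"]][-1]
      if (any(is.finite(pv)) && min(pv, na.rm = TRUE) < p_enter) {
        in_model <- c(in_model, cand[which.min(pv)])
        changed <- TRUE
      }
    }
    repeat {
      if (length(in_model) == 0) break
      form <- stats::reformulate(in_model, response = ".y")
      fit <- stats::lm(form, data = dat)
      d1 <- stats::drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      if (max(pv, na.rm = TRUE) > p_remove) {
        in_model <- setdiff(in_model, in_model[which.max(pv)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  form <- stats::reformulate(if (length(in_model)) in_model else "1",
                             response = ".y")
  fit <- stats::lm(form, data = dat)
  cf <- stats::coef(fit)
  sel <- labels[match(in_model, safe)]
  names(cf) <- c("(Intercept)", sel)[seq_along(cf)]
  list(selected = sort(sel), coef = cf)
}

# Cook's distance by explicit leave-one-out refits
oracle_cooks <- function(Xs, y) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs), crossprod(Xs, y))
  yhat <- drop(Xs %*% beta)
  s2 <- sum((y - yhat)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    bi <- solve(crossprod(Xs[-i, , drop = FALSE]),
                crossprod(Xs[-i, , drop = FALSE], y[-i]))
    sum((yhat - drop(Xs %*% bi))^2) / (p * s2)
  }, numeric(1))
}

# tiny two-drug truth with prescribed monotherapy viabilities at dose 1 uM
toy_truth <- function(v1 = 0.8, v2 = 0.8, psi12 = 0, noise_sd = 0,
                      h = 1, line = "cell") {
  drugs <- c("a", "b")
  hill <- tibble::tibble(drug = rep(drugs, 1),
                         cell_line = line,
                         ic50_uM = c(v1 / (1 - v1), v2 / (1 - v2))^(1 / h),
                         h = h)
  psi <- matrix(c(0, psi12, psi12, 0), 2, dimnames = list(drugs, drugs))
  truth_params(drugs, line, hill, psi = setNames(list(psi), line),
               noise_sd = noise_sd)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
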