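# Orthogonal array composite designs (OACD): a two-level factorial fraction
# at coded levels {0, 2} (clear main effects and two-factor interactions), a
# standard three-level orthogonal array at {0, 1, 2} (curvature), and one
# all-zero vehicle/center run.

# Greedy resolution-V column selection over the effect columns of a 2^m full
# factorial. Columns are bitmasks of base factors; a set is resolution >= V
# iff all pairwise XORs are nonzero, mutually distinct, and distinct from the
# chosen columns themselves (no defining word of length <= 4).
pick_resv_columns <- function(k, m) {
  all_cols <- seq_len(2^m - 1)
  weight <- vapply(all_cols, function(b) sum(bitwAnd(b, 2^(0:(m - 1))) > 0), 0)
  cand <- all_cols[order(weight, all_cols)]
  chosen <- integer(0)
  pair_xor <- integer(0)
  for (b in cand) {
    new_pairs <- bitwXor(chosen, b)
    if (any(new_pairs == 0)) next
    trial_pairs <- c(pair_xor, new_pairs)
    if (anyDuplicated(trial_pairs) ||
        any(trial_pairs %in% c(chosen, b))) next
    chosen <- c(chosen, b)
    pair_xor <- trial_pairs
    if (length(chosen) == k) return(chosen)
  }
  NULL
}

two_level_fraction <- function(k) {
  if (k <= 4) {
    g <- as.matrix(rev(expand.grid(rep(list(c(0, 2)), k))))
    colnames(g) <- NULL
    return(g[, seq_len(k), drop = FALSE])
  }
  for (m in ceiling(log2(k + 1)):14) {
    cols <- pick_resv_columns(k, m)
    if (!is.null(cols)) {
      base <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
      D <- vapply(cols, function(b) {
        idx <- which(bitwAnd(b, 2^(0:(m - 1))) > 0)
        apply(base[, idx, drop = FALSE], 1, prod)
      }, numeric(nrow(base)))
      return(D + 1)  # map {-1, 1} -> {0, 2}
    }
  }
  abort("No two-level fraction of resolution >= V found (fallback exhausted).",
        class = "tgmo_design_error")
}

# Taguchi L18 (the seven three-level columns), a strength-2 OA(18, 3^7).
oa18_table <- function() {
  matrix(c(
    0, 0, 0, 0, 0, 0, 0,
    0, 1, 1, 1, 1, 1, 1,
    0, 2, 2, 2, 2, 2, 2,
    1, 0, 0, 1, 1, 2, 2,
    1, 1, 1, 2, 2, 0, 0,
    1, 2, 2, 0, 0, 1, 1,
    2, 0, 1, 0, 2, 1, 2,
    2, 1, 2, 1, 0, 2, 0,
    2, 2, 0, 2, 1, 0, 1,
    0, 0, 2, 2, 1, 1, 0,
    0, 1, 0, 0, 2, 2, 1,
    0, 2, 1, 1, 0, 0, 2,
    1, 0, 1, 2, 0, 2, 1,
    1, 1, 2, 0, 1, 0, 2,
    1, 2, 0, 1, 2, 1, 0,
    2, 0, 2, 1, 2, 0, 1,
    2, 1, 0, 2, 0, 1, 2,
    2, 2, 1, 0, 1, 2, 0), ncol = 7, byrow = TRUE)
}

# OA(27, 3^13): linear forms a*u + b*v + c*w over GF(3), one column per
# direction (first nonzero coefficient equal to 1).
oa27_table <- function() {
  g <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  coefs <- list()
  for (a in 0:2) for (b in 0:2) for (cc in 0:2) {
    v <- c(a, b, cc)
    if (all(v == 0)) next
    if (v[which(v != 0)[1]] == 1) coefs[[length(coefs) + 1]] <- v
  }
  cols <- vapply(coefs, function(v) as.numeric((g %*% v) %% 3), numeric(27))
  cols
}

three_level_block <- function(k) {
  if (k <= 3) {
    g <- as.matrix(rev(expand.grid(rep(list(0:2), k))))
    colnames(g) <- NULL
    g[, seq_len(k), drop = FALSE]
  } else if (k <= 7) {
    oa18_table()[, seq_len(k), drop = FALSE]
  } else if (k <= 13) {
    oa27_table()[, seq_len(k), drop = FALSE]
  } else {
    abort("Three-level orthogonal arrays provided only up to 13 drugs.",
          class = "tgmo_design_error")
  }
}

#' Generate an orthogonal array composite design
#'
#' Builds the coded run table for a k-drug combination screen: a regular
#' two-level fraction at levels \{0, 2\} of resolution at least V (full
#' factorial for k <= 4), k columns of a standard three-level orthogonal
#' array (full 3^k for k <= 3, OA(18, 3^7) for k <= 7, OA(27, 3^13) for
#' k <= 13) at levels \{0, 1, 2\}, and one all-zero vehicle/center run.
#' Duplicate runs across blocks are collapsed (first occurrence kept, with
#' multiplicity recorded) and the measurement order is randomized
#' reproducibly by `seed`.
#'
#' Coded levels mean: 0 = drug absent, 1 = half dose, 2 = screening dose.
#'
#' @param k Number of drugs, between 2 and 13.
#' @param drugs Optional character vector of k drug names (defaults to
#'   `drug01`, `drug02`, ...).
#' @param seed Integer seed fixing the run order.
#'
#' @return A `tgmo_design` tibble with columns `run_id`, `block`
#'   (`two_level`, `three_level` or `center`), `multiplicity`, and one coded
#'   column per drug; drug order kept in `attr(, "drug_order")`.
#' @export
#' @examples
#' generate_oacd(3, drugs = c("a", "b", "c"), seed = 1)
generate_oacd <- function(k, drugs = NULL, seed = 1L) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 2 || k > 13) {
    abort("k must be an integer between 2 and 13.",
          class = "tgmo_validation_error")
  }
  k <- as.integer(k)
  if (is.null(drugs)) drugs <- sprintf("drug%02d", seq_len(k))
  if (length(drugs) != k || anyDuplicated(drugs)) {
    abort("'drugs' must supply k distinct names.",
          class = "tgmo_validation_error")
  }

  tl <- two_level_fraction(k)
  th <- three_level_block(k)
  runs <- rbind(tl, th, rep(0, k))
  block <- c(rep("two_level", nrow(tl)), rep("three_level", nrow(th)), "center")

  key <- apply(runs, 1, paste, collapse = ",")
  first <- !duplicated(key)
  multiplicity <- as.integer(table(key)[key[first]])
  runs <- runs[first, , drop = FALSE]
  block <- block[first]
  # the center run label wins for the all-zero condition
  zero_key <- paste(rep(0, k), collapse = ",")
  block[key[first] == zero_key] <- "center"

  n <- nrow(runs)
  ord <- withr::with_seed(as.integer(seed), sample.int(n))
  runs <- runs[ord, , drop = FALSE]
  block <- block[ord]
  multiplicity <- multiplicity[ord]

  colnames(runs) <- drugs
  out <- tibble::as_tibble(as.data.frame(runs))
  out <- dplyr::bind_cols(
    tibble::tibble(run_id = sprintf("R%03d", seq_len(n)),
                   block = block,
                   multiplicity = multiplicity),
    out)
  attr(out, "drug_order") <- drugs
  attr(out, "k") <- k
  attr(out, "seed") <- as.integer(seed)
  # constructed blocks pre-deduplication, for balance/orthogonality checks
  colnames(th) <- drugs
  attr(out, "three_level_block") <- th
  class(out) <- c("tgmo_design", class(out))
  out
}

#' Extract the coded-level matrix of a design
#'
#' @param design A `tgmo_design`.
#' @return Numeric matrix, runs by drugs.
#' @export
design_levels <- function(design) {
  drugs <- attr(design, "drug_order")
  m <- as.matrix(design[, drugs, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- design$run_id
  m
}

#' Validate a design against a model order
#'
#' Checks estimability and balance: whether the model matrix for the
#' requested model has full column rank, the level counts per drug within
#' the three-level block, the maximum absolute pairwise correlation between
#' model-matrix columns, and the D-efficiency
#' `det(X'X)^(1/p) / n` computed on the standardized model matrix.
#'
#' @param design A `tgmo_design`.
#' @param model_order `"full_quadratic"` (intercept, linear, quadratic and
#'   all pairwise interaction terms) or `"linear"`.
#'
#' @return A list: `rank_ok`, `rank`, `p`, `balance` (tibble), `max_cor`,
#'   `d_efficiency`.
#' @export
validate_design <- function(design, model_order = c("full_quadratic", "linear")) {
  model_order <- match.arg(model_order)
  if (nrow(design) == 0) {
    abort("Empty design.", class = "tgmo_validation_error")
  }
  L <- design_levels(design)
  X <- model_matrix_from_levels(L, quadratic = model_order == "full_quadratic")
  p <- ncol(X)
  r <- qr(X)$rank

  # balance is a property of the constructed three-level array (duplicate
  # collapse against the other blocks does not change what was designed)
  tri_block <- attr(design, "three_level_block")
  if (is.null(tri_block)) tri_block <- L[design$block == "three_level", ,
                                         drop = FALSE]
  balance <- purrr::map_dfr(colnames(L), function(d) {
    counts <- table(factor(tri_block[, d], levels = 0:2))
    tibble::tibble(drug = d,
                   level0 = as.integer(counts[["0"]]),
                   level1 = as.integer(counts[["1"]]),
                   level2 = as.integer(counts[["2"]]))
  })

  Xs <- X[, -1, drop = FALSE]
  keep <- apply(Xs, 2, function(z) sd(z) > 0)
  max_cor <- if (sum(keep) >= 2) {
    cc <- stats::cor(Xs[, keep, drop = FALSE])
    max(abs(cc[upper.tri(cc)]))
  } else NA_real_

  d_eff <- if (r == p) {
    Z <- cbind(1, scale(Xs))
    Z[is.na(Z)] <- 0
    det(crossprod(Z))^(1 / p) / nrow(Z)
  } else 0

  list(rank_ok = r == p, rank = r, p = p, balance = balance,
       max_cor = max_cor, d_efficiency = d_eff)
}

#' Map coded levels to concentrations
#'
#' Level 0 maps to 0 µM, level 1 to the half dose, level 2 to the screening
#' dose of each drug.
#'
#' @param design A `tgmo_design`.
#' @param specs A `drug_specs()` tibble covering every drug in the design.
#'
#' @return Tibble: `run_id` plus one concentration column (µM) per drug.
#' @export
map_to_concentrations <- function(design, specs) {
  drugs <- attr(design, "drug_order")
  missing_spec <- setdiff(drugs, specs$drug)
  if (length(missing_spec) > 0) {
    abort(paste0("No dose specification for: ",
                 paste(missing_spec, collapse = ", ")),
          class = "tgmo_validation_error")
  }
  L <- design_levels(design)
  conc <- vapply(drugs, function(d) {
    s <- specs[specs$drug == d, ]
    c(0, s$half_dose_uM, s$screen_dose_uM)[L[, d] + 1]
  }, numeric(nrow(L)))
  conc <- matrix(conc, nrow = nrow(L),
                 dimnames = list(NULL, drugs))
  dplyr::bind_cols(tibble::tibble(run_id = design$run_id),
                   tibble::as_tibble(as.data.frame(conc)))
}

#' Write a design (and optionally its concentration map) to CSV
#'
#' @param design A `tgmo_design`.
#' @param path Output path for the coded design.
#' @param specs Optional `drug_specs()` tibble; when given, a companion
#'   `*_uM.csv` with concentrations is written next to `path`.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path, specs = NULL) {
  readr::write_csv(as.data.frame(design), path)
  if (!is.null(specs)) {
    conc_path <- sub("\\.csv$", "_uM.csv", path)
    readr::write_csv(map_to_concentrations(design, specs), conc_path)
  }
  invisible(path)
}
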