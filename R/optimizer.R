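# Translation of fitted coefficients into per-drug evidence, drug
# elimination, dose refinement, and the multi-round search orchestrator.

#' Classify model terms as beneficial, detrimental or neutral
#'
#' Sign conventions follow the endpoint: a positive coefficient means
#' reduced cellular activity, which is desirable on the therapeutic-window
#' endpoint but undesirable on the cancer-viability endpoint. Terms whose
#' p-value is at or above `alpha_sig` are neutral. A detrimental interaction
#' on the cancer endpoint is antagonism; a beneficial one is synergy.
#'
#' @param model A `tgmo_model`.
#' @param alpha_sig Significance level for a non-neutral call (default
#'   0.05).
#'
#' @return Tibble of non-intercept terms: `term`, `kind`, `i`, `j`, `beta`,
#'   `p_value`, `endpoint`, `call`.
#' @export
classify_terms <- function(model, alpha_sig = 0.05) {
  tt <- model$terms[model$terms$kind != "intercept", ]
  if (nrow(tt) == 0) {
    return(tibble::tibble(term = character(0), kind = character(0),
                          i = integer(0), j = integer(0),
                          beta = numeric(0), p_value = numeric(0),
                          endpoint = character(0), call = character(0)))
  }
  sig <- !is.na(tt$p_value) & tt$p_value < alpha_sig
  benef_sign <- if (model$endpoint == "cancer_viability") tt$beta < 0 else tt$beta > 0
  call <- dplyr::case_when(!sig ~ "neutral",
                           benef_sign ~ "beneficial",
                           TRUE ~ "detrimental")
  tibble::tibble(term = tt$label, kind = tt$kind, i = tt$i, j = tt$j,
                 beta = tt$beta, p_value = tt$p_value,
                 endpoint = model$endpoint, call = call)
}

#' Assemble the per-drug evidence ledger of one screen round
#'
#' Gathers, for each active drug, the monotherapy effect at its level-2
#' dose, its toxicity alone on the non-malignant line, and the counts of
#' significant beneficial/detrimental terms (interactions and linear main
#' effects) it participates in across the classified endpoints.
#'
#' @param classes Combined [classify_terms()] output across endpoints.
#' @param drugs Active drug names in design order (term indices `i`, `j`
#'   refer to this order).
#' @param mono Tibble with `drug`, `cancer_viability`, `normal_viability`:
#'   mean monotherapy viabilities at the level-2 dose.
#' @param tox_threshold Normal-line viability threshold (default 80).
#'
#' @return A `drug_ledger` tibble.
#' @export
build_drug_ledger <- function(classes, drugs, mono, tox_threshold = 80) {
  count_for <- function(idx, kinds, call) {
    sum(classes$call == call & classes$kind %in% kinds &
          (classes$i == idx | (!is.na(classes$j) & classes$j == idx)),
        na.rm = TRUE)
  }
  out <- purrr::map_dfr(seq_along(drugs), function(idx) {
    d <- drugs[idx]
    m <- mono[mono$drug == d, ]
    tibble::tibble(
      drug = d,
      monotherapy_effect = m$cancer_viability,
      normal_viability = m$normal_viability,
      toxic_alone = flag_toxicity(m$normal_viability,
                                  threshold = tox_threshold),
      detrimental_interactions = count_for(idx, "interaction", "detrimental"),
      beneficial_interactions = count_for(idx, "interaction", "beneficial"),
      detrimental_mains = count_for(idx, "linear", "detrimental"),
      beneficial_mains = count_for(idx, "linear", "beneficial")
    )
  })
  class(out) <- c("drug_ledger", class(out))
  out
}

#' Eliminate detrimental drugs from the search
#'
#' Scores each drug by its detriment: significant detrimental interactions
#' on either endpoint, toxicity of the drug alone on the non-malignant
#' line, and detrimental main effects, combined with configurable weights.
#' Up to `max_removals` drugs with strictly positive scores are removed,
#' highest score first; ties are broken by the weaker monotherapy effect
#' (higher viability alone), then drug name. An empty removal set signals
#' convergence.
#'
#' @param ledger A `drug_ledger` from [build_drug_ledger()].
#' @param max_removals Maximum drugs removed per round (default 3).
#' @param weights Named numeric weights `interaction`, `toxicity`, `main`
#'   (defaults 1, 2, 1).
#'
#' @return List: `removed` (character), `ledger` (with `score`, `decision`,
#'   `reasons` columns).
#' @export
eliminate_drugs <- function(ledger, max_removals = 3,
                            weights = c(interaction = 1, toxicity = 2,
                                        main = 1)) {
  if (nrow(ledger) < 3) {
    abort("Elimination requires at least 3 active drugs.",
          class = "tgmo_validation_error")
  }
  led <- dplyr::mutate(
    ledger,
    score = weights[["interaction"]] * .data$detrimental_interactions +
      weights[["toxicity"]] * as.numeric(.data$toxic_alone) +
      weights[["main"]] * .data$detrimental_mains)
  ranked <- led |>
    dplyr::filter(.data$score > 0) |>
    dplyr::arrange(dplyr::desc(.data$score),
                   dplyr::desc(.data$monotherapy_effect),
                   .data$drug)
  removed <- head(ranked$drug, max_removals)
  led$decision <- ifelse(led$drug %in% removed, "eliminate", "keep")
  led$reasons <- purrr::pmap_chr(led, function(...) {
    r <- list(...)
    if (!r$drug %in% removed) return("")
    parts <- c(
      if (r$detrimental_interactions > 0)
        paste0(r$detrimental_interactions, " detrimental interaction(s)"),
      if (r$toxic_alone) "toxic alone on the non-malignant line",
      if (r$detrimental_mains > 0)
        paste0(r$detrimental_mains, " detrimental main effect(s)"))
    paste(parts, collapse = "; ")
  })
  list(removed = removed, ledger = led)
}

# Enroll the best four drugs when the search converges with more than four
# still active: non-toxic first, then most beneficial evidence, then the
# stronger monotherapy effect.
select_final_four <- function(ledger) {
  ledger |>
    dplyr::arrange(.data$toxic_alone,
                   dplyr::desc(.data$beneficial_interactions +
                                 .data$beneficial_mains),
                   .data$monotherapy_effect,
                   .data$drug) |>
    dplyr::pull(.data$drug) |>
    head(4)
}

#' Escalate screening doses under the clinical cap
#'
#' Doubles (by default) each level-2 dose, capped at the clinically used
#' dose; drugs already screened at their CUD are unchanged. Half doses are
#' re-derived.
#'
#' @param specs A `drug_specs()` tibble.
#' @param escalation Multiplicative factor (default 2).
#'
#' @return Updated `drug_specs()` tibble.
#' @export
#' @examples
#' refine_doses(drug_specs("vismodegib", 17.0, 6.377))
refine_doses <- function(specs, escalation = 2) {
  new_dose <- pmin(escalation * specs$screen_dose_uM, specs$cud_uM)
  drug_specs(specs$drug, specs$cud_uM, new_dose)
}

# deterministic sub-seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, a = 0, b = 0, c = 0) {
  as.integer((as.numeric(seed) * 1000003 + a * 8191 + b * 127 + c) %%
               2147483629)
}

tgmo_config <- function(replicates = 3, p_enter = 0.05, p_remove = 0.10,
                        alpha_sig = 0.05, tox_threshold = 80,
                        max_removals = 3, max_rounds = 5, escalation = 2,
                        weights = c(interaction = 1, toxicity = 2, main = 1),
                        cooks_rule = "3x_mean") {
  list(replicates = replicates, p_enter = p_enter, p_remove = p_remove,
       alpha_sig = alpha_sig, tox_threshold = tox_threshold,
       max_removals = max_removals, max_rounds = max_rounds,
       escalation = escalation, weights = weights, cooks_rule = cooks_rule)
}

measure_runs <- function(measure, conc, lines, replicates, seed) {
  purrr::imap(setNames(lines, lines), function(ln, nm) {
    measure(conc, ln, replicates, derive_seed(seed, match(nm, lines)))
  })
}

run_round <- function(measure, specs, cancer_line, normal_line, cfg,
                      seed_base) {
  k <- nrow(specs)
  design <- generate_oacd(k, drugs = specs$drug, seed = seed_base)
  conc <- map_to_concentrations(design, specs)

  meas <- measure_runs(measure, conc, c(cancer_line, normal_line),
                       cfg$replicates, derive_seed(seed_base, 1))
  y_cancer <- meas[[cancer_line]]
  y_normal <- meas[[normal_line]]

  tw <- dplyr::inner_join(
    dplyr::select(y_normal, "run_id", "replicate", normal = "viability_pct"),
    dplyr::select(y_cancer, "run_id", "replicate", cancer = "viability_pct"),
    by = c("run_id", "replicate"))
  tw$tw <- compute_tw(tw$normal, tw$cancer)

  m_cancer <- fit_response_model(design, y_cancer, "cancer_viability",
                                 replicates = cfg$replicates,
                                 p_enter = cfg$p_enter,
                                 p_remove = cfg$p_remove,
                                 cooks_rule = cfg$cooks_rule)
  m_tw <- fit_response_model(design, tw, "therapeutic_window", value = "tw",
                             replicates = cfg$replicates,
                             p_enter = cfg$p_enter, p_remove = cfg$p_remove,
                             cooks_rule = cfg$cooks_rule)

  # monotherapy arms: each active drug alone at its level-2 dose
  mono_conc <- diag(specs$screen_dose_uM, nrow = k)
  colnames(mono_conc) <- specs$drug
  mono_conc <- dplyr::bind_cols(
    tibble::tibble(run_id = sprintf("M%03d", seq_len(k))),
    tibble::as_tibble(as.data.frame(mono_conc)))
  mono_meas <- measure_runs(measure, mono_conc, c(cancer_line, normal_line),
                            cfg$replicates, derive_seed(seed_base, 2))
  mono <- tibble::tibble(
    drug = specs$drug,
    cancer_viability = summarise_screen(mono_meas[[cancer_line]])$mean[
      match(mono_conc$run_id,
            summarise_screen(mono_meas[[cancer_line]])$run_id)],
    normal_viability = summarise_screen(mono_meas[[normal_line]])$mean[
      match(mono_conc$run_id,
            summarise_screen(mono_meas[[normal_line]])$run_id)])

  classes <- dplyr::bind_rows(classify_terms(m_cancer, cfg$alpha_sig),
                              classify_terms(m_tw, cfg$alpha_sig))
  ledger <- build_drug_ledger(classes, specs$drug, mono,
                              tox_threshold = cfg$tox_threshold)
  list(design = design, specs = specs,
       models = list(cancer_viability = m_cancer,
                     therapeutic_window = m_tw),
       classes = classes, mono = mono, ledger = ledger)
}

measure_full_combo <- function(measure, specs, cancer_line, normal_line,
                               cfg, seed_base) {
  conc <- matrix(specs$screen_dose_uM, nrow = 1,
                 dimnames = list(NULL, specs$drug))
  conc <- dplyr::bind_cols(tibble::tibble(run_id = "FULL"),
                           tibble::as_tibble(as.data.frame(conc)))
  meas <- measure_runs(measure, conc, c(cancer_line, normal_line),
                       cfg$replicates, seed_base)
  v_c <- mean(meas[[cancer_line]]$viability_pct)
  v_n <- mean(meas[[normal_line]]$viability_pct)
  tibble::tibble(cancer_viability = v_c, normal_viability = v_n,
                 tw = compute_tw(v_n, v_c))
}

# ODC emission from a final-round result: drop toxic or antagonistic drugs,
# then emit the combined, synergistic-core and purely-additive variants.
emit_odcs <- function(round_out, cfg) {
  specs <- round_out$specs
  ledger <- round_out$ledger
  classes <- round_out$classes
  drugs <- specs$drug

  # eligibility for the final combination is judged on the efficacy
  # endpoint: antagonism means a detrimental interaction on cancer
  # viability (the therapeutic-window side keeps informing elimination
  # rounds, not this final call). Each antagonistic pair is resolved by
  # dropping the member with the lesser beneficial contribution.
  inter_cancer <- classes[classes$kind == "interaction" &
                            classes$endpoint == "cancer_viability", ]
  # an enrolled drug must be non-toxic and carry some beneficial evidence
  # (a significant beneficial main effect or interaction on any endpoint)
  eligible <- ledger$drug[!ledger$toxic_alone &
                            (ledger$beneficial_mains > 0 |
                               ledger$beneficial_interactions > 0)]
  benefit_rank <- function(d) {
    row <- ledger[ledger$drug == d, ]
    c(row$beneficial_interactions, row$beneficial_mains,
      -row$monotherapy_effect)
  }
  repeat {
    det <- inter_cancer[inter_cancer$call == "detrimental" &
                          drugs[inter_cancer$i] %in% eligible &
                          drugs[inter_cancer$j] %in% eligible, ]
    if (nrow(det) == 0) break
    worst <- det[which.max(det$beta), ]
    pair <- c(drugs[worst$i], drugs[worst$j])
    ranks <- lapply(pair, benefit_rank)
    cmp <- mapply(function(a, b) sign(a - b), ranks[[1]], ranks[[2]])
    first_diff <- cmp[cmp != 0][1]
    drop_drug <- if (is.na(first_diff)) max(pair) else
      if (first_diff < 0) pair[1] else pair[2]
    eligible <- setdiff(eligible, drop_drug)
  }
  if (length(eligible) < 2) {
    return(list(odcs = tibble::tibble(odc = character(0), type = character(0),
                                      drug = character(0),
                                      dose_uM = numeric(0)),
                eligible = eligible))
  }
  dose_of <- setNames(specs$screen_dose_uM, specs$drug)

  variants <- list()
  variants[["combined"]] <- eligible

  inter <- inter_cancer
  benef_pairs <- inter[inter$call == "beneficial", ]
  # keep only pairs whose both members are eligible
  core_ok <- unique(unlist(purrr::map2(benef_pairs$i, benef_pairs$j,
                                       function(a, b) {
    da <- drugs[a]; db <- drugs[b]
    if (da %in% eligible && db %in% eligible) c(da, db) else character(0)
  })))
  if (length(core_ok) >= 2) variants[["synergistic"]] <- core_ok

  # purely additive: beneficial mains, no significant interaction within
  main_benef <- ledger$drug[ledger$beneficial_mains > 0 &
                              ledger$drug %in% eligible]
  sig_pair <- function(set) {
    idx <- match(set, drugs)
    rows <- inter[inter$call != "neutral" & inter$i %in% idx &
                    inter$j %in% idx, ]
    rows
  }
  add_set <- main_benef
  cancer_main <- classes[classes$kind == "linear" &
                           classes$endpoint == "cancer_viability", ]
  main_strength <- setNames(rep(0, length(drugs)), drugs)
  main_strength[drugs[cancer_main$i]] <- -cancer_main$beta  # larger = stronger kill
  while (length(add_set) >= 2) {
    bad <- sig_pair(add_set)
    if (nrow(bad) == 0) break
    pair <- c(drugs[bad$i[1]], drugs[bad$j[1]])
    weaker <- pair[which.min(main_strength[pair])]
    add_set <- setdiff(add_set, weaker)
  }
  if (length(add_set) >= 2) variants[["additive"]] <- sort(add_set)

  # drop duplicated member sets, keep first (combined > synergistic > additive)
  seen <- character(0)
  odcs <- purrr::imap_dfr(variants, function(set, type) {
    key <- paste(sort(set), collapse = "|")
    if (key %in% seen) return(NULL)
    seen <<- c(seen, key)
    tibble::tibble(odc = paste0("ODC_", type), type = type,
                   drug = sort(set), dose_uM = unname(dose_of[sort(set)]))
  })
  list(odcs = odcs, eligible = eligible)
}

#' Run a full multi-round combination search
#'
#' Orchestrates the iterative search for one or more cancer lines against a
#' shared non-malignant line: each round builds an orthogonal array
#' composite design over the active drugs, measures (or simulates) the
#' screen, fits the stepwise second-order models on the cancer-viability
#' and therapeutic-window endpoints, classifies terms, assembles the drug
#' ledger and eliminates detrimental drugs. When the search converges on at
#' most four drugs, a final dose-refinement round compares the current
#' doses against escalated doses (capped at the clinically used dose) and
#' emits the optimized drug combinations: the combined set of non-toxic,
#' non-antagonistic drugs, the synergistic core, and (when present) a
#' purely additive variant.
#'
#' @param measure Measurement function `(conc, cell_line, replicates, seed)`
#'   returning viability records; see [make_measure_fn()] for the simulator
#'   adapter.
#' @param drugs Tibble with `drug`, `cud_uM`, `screen_dose_uM`.
#' @param cancer_lines Character vector of cancer line names; one
#'   independent search is run per line.
#' @param normal_line Name of the non-malignant line.
#' @param seed Integer master seed; every round's randomness derives from
#'   it.
#' @param ... Configuration overrides passed to the internal config
#'   (replicates, p_enter, p_remove, alpha_sig, tox_threshold,
#'   max_removals, max_rounds, escalation, weights, cooks_rule).
#'
#' @return A `tgmo_search` object: per-line traces (`rounds`, `final`),
#'   emitted `odcs` tibble, and `status`.
#' @export
tgmo_run <- function(measure, drugs, cancer_lines, normal_line,
                     seed = 1L, ...) {
  cfg <- tgmo_config(...)
  specs0 <- drug_specs(drugs$drug, drugs$cud_uM, drugs$screen_dose_uM)

  searches <- purrr::imap(setNames(cancer_lines, cancer_lines),
                          function(line, nm) {
    li <- match(line, cancer_lines)
    run_search(measure, specs0, line, normal_line, cfg,
               seed_base = derive_seed(seed, 0, li))
  })
  odcs <- dplyr::bind_rows(purrr::imap(searches, function(s, line) {
    dplyr::mutate(s$odcs, cell_line = line, .before = 1)
  }))
  status <- if (all(purrr::map_chr(searches, "status") == "converged") &&
                nrow(odcs) > 0) "converged" else "failed"
  reason <- if (nrow(odcs) == 0) "no beneficial terms" else NA_character_
  structure(list(searches = searches, odcs = odcs, status = status,
                 reason = reason, config = cfg, seed = as.integer(seed)),
            class = "tgmo_search")
}

run_search <- function(measure, specs0, cancer_line, normal_line, cfg,
                       seed_base) {
  specs <- specs0
  rounds <- list()
  status <- "running"
  r <- 0L
  while (TRUE) {
    r <- r + 1L
    if (r > cfg$max_rounds) {
      status <- "max_rounds_reached"
      break
    }
    out <- run_round(measure, specs, cancer_line, normal_line, cfg,
                     derive_seed(seed_base, 0, 0, r))
    if (nrow(specs) <= 4) {
      # enrollment reached: detrimental drugs are handled by the final
      # eligibility rule, not by further elimination rounds
      out$removed <- character(0)
      rounds[[r]] <- out
      status <- "converged"
      break
    }
    elim <- eliminate_drugs(out$ledger, max_removals = cfg$max_removals,
                            weights = cfg$weights)
    out$ledger <- elim$ledger
    out$removed <- elim$removed
    rounds[[r]] <- out
    remaining <- setdiff(specs$drug, elim$removed)
    if (length(elim$removed) > 0 && length(remaining) >= 2) {
      specs <- specs[specs$drug %in% remaining, ]
      next
    }
    enrolled <- select_final_four(out$ledger)
    specs <- specs[specs$drug %in% enrolled, ]
  }

  if (status != "converged") {
    return(list(cancer_line = cancer_line, rounds = rounds, final = NULL,
                odcs = tibble::tibble(odc = character(0), type = character(0),
                                      drug = character(0),
                                      dose_uM = numeric(0)),
                status = status))
  }

  # final dose-refinement phase: (i) current doses (converged round reused),
  # (ii) escalated doses capped at the CUD
  last <- rounds[[length(rounds)]]
  specs_hi <- refine_doses(specs, escalation = cfg$escalation)
  out_hi <- run_round(measure, specs_hi, cancer_line, normal_line, cfg,
                      derive_seed(seed_base, 0, 0, 50))
  combo_lo <- measure_full_combo(measure, specs, cancer_line, normal_line,
                                 cfg, derive_seed(seed_base, 0, 0, 70))
  combo_hi <- measure_full_combo(measure, specs_hi, cancer_line, normal_line,
                                 cfg, derive_seed(seed_base, 0, 0, 71))
  pick_hi <- combo_hi$tw >= combo_lo$tw
  chosen <- if (pick_hi) out_hi else last
  emitted <- emit_odcs(chosen, cfg)

  list(cancer_line = cancer_line, rounds = rounds,
       final = list(variant_current = list(round = last, combo = combo_lo),
                    variant_escalated = list(round = out_hi,
                                             combo = combo_hi),
                    chosen = if (pick_hi) "escalated" else "current",
                    eligible = emitted$eligible),
       odcs = emitted$odcs, status = "converged")
}

#' @export
print.tgmo_search <- function(x, ...) {
  cat("<tgmo_search>", x$status, "\n")
  for (nm in names(x$searches)) {
    s <- x$searches[[nm]]
    cat("  ", nm, ": ", length(s$rounds), " round(s), status ", s$status,
        "\n", sep = "")
  }
  if (nrow(x$odcs) > 0) {
    cat("  optimized combinations:\n")
    print(x$odcs, n = Inf)
  } else {
    cat("  no combination emitted (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

#' @method tidy tgmo_search
#' @export
tidy.tgmo_search <- function(x, ...) {
  x$odcs
}

#' Write the combinations and search trace of a run to JSON
#'
#' Produces `odc.json` (one drug-to-dose map per emitted combination) and
#' `search_trace.json` (round-by-round eliminations) in `dir`.
#'
#' @param x A `tgmo_search`.
#' @param dir Output directory (created if absent).
#' @return The two file paths, invisibly.
#' @export
write_search_json <- function(x, dir = ".") {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_search_json requires the 'jsonlite' package.")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  odc_path <- file.path(dir, "odc.json")
  trace_path <- file.path(dir, "search_trace.json")
  odc_list <- list()
  if (nrow(x$odcs) > 0) {
    sp <- split(x$odcs, paste(x$odcs$cell_line, x$odcs$odc, sep = "/"))
    odc_list <- lapply(sp, function(d) as.list(setNames(d$dose_uM, d$drug)))
  }
  jsonlite::write_json(odc_list, odc_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(status = x$status, seed = x$seed,
                            trace = search_trace(x)),
                       trace_path, auto_unbox = TRUE, digits = NA)
  invisible(c(odc_path, trace_path))
}

#' Round-by-round elimination history of a search
#'
#' @param x A `tgmo_search`.
#' @return Tibble: `cell_line`, `round`, `k`, `removed`.
#' @export
search_trace <- function(x) {
  purrr::imap_dfr(x$searches, function(s, line) {
    purrr::imap_dfr(s$rounds, function(r, i) {
      tibble::tibble(cell_line = line, round = i, k = nrow(r$specs),
                     removed = paste(r$removed, collapse = ";"))
    })
  })
}
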