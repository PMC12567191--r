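#' Normalize raw well signal to the vehicle control
#'
#' Converts a raw luminescence (or other viability-proportional) signal into
#' percent viability relative to the mean of the vehicle-control wells on the
#' same plate. Vehicle wells therefore average to exactly 100 by construction.
#'
#' @param raw_signal Numeric vector of non-negative raw well signals.
#' @param vehicle_signals Non-empty numeric vector of raw signals from the
#'   vehicle-control wells of the same plate.
#' @param plate Optional plate label used in error messages.
#'
#' @return Numeric vector of viability values in percent of vehicle control.
#' @export
#' @examples
#' normalize_to_vehicle(5000, c(9000, 10000, 11000))
normalize_to_vehicle <- function(raw_signal, vehicle_signals, plate = NULL) {
  where <- if (is.null(plate)) "" else paste0(" on plate '", plate, "'")
  if (length(vehicle_signals) == 0 || all(is.na(vehicle_signals))) {
    abort(paste0("No vehicle-control signals available", where, "."),
          class = "tgmo_normalization_error")
  }
  if (any(raw_signal < 0, na.rm = TRUE) || any(vehicle_signals < 0, na.rm = TRUE)) {
    abort("Raw signals must be non-negative.", class = "tgmo_validation_error")
  }
  m <- mean(vehicle_signals, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    abort(paste0("Vehicle-control mean is zero or non-finite", where,
                 "; cannot normalize."),
          class = "tgmo_normalization_error")
  }
  100 * raw_signal / m
}

#' Aggregate replicate viability values
#'
#' Summarises replicate measurements of one condition into mean, sample
#' standard deviation (n - 1 denominator) and replicate count. A single
#' replicate yields a missing standard deviation with a warning.
#'
#' @param values Numeric vector of viability percentages (n >= 1).
#'
#' @return A one-row tibble with columns `mean`, `sd`, `n`.
#' @export
#' @examples
#' aggregate_replicates(c(70, 80, 90))
aggregate_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) {
    abort("Cannot aggregate zero replicates.", class = "tgmo_validation_error")
  }
  s <- if (n == 1) {
    warn("Single replicate: standard deviation reported as missing.")
    NA_real_
  } else {
    sd(values)
  }
  tibble::tibble(mean = mean(values), sd = s, n = n)
}

#' Flag toxicity on the non-malignant line
#'
#' A condition is called toxic when viability of the non-malignant (healthy)
#' cell line drops below the threshold, 80% of vehicle control by default.
#' The boundary itself is non-toxic under the default strict-below rule.
#'
#' @param viability_pct_normal Numeric vector of normal-line viability values
#'   (% of vehicle control), non-negative.
#' @param threshold Toxicity threshold in percent viability (default 80).
#' @param strict If `TRUE` (default) toxicity requires viability strictly
#'   below the threshold; if `FALSE`, at-or-below.
#'
#' @return Logical vector: `TRUE` where the condition is toxic.
#' @export
#' @examples
#' flag_toxicity(c(79.1, 80, 95))
flag_toxicity <- function(viability_pct_normal, threshold = 80, strict = TRUE) {
  if (any(viability_pct_normal < 0, na.rm = TRUE)) {
    abort("Viability must be non-negative.", class = "tgmo_validation_error")
  }
  if (strict) viability_pct_normal < threshold else viability_pct_normal <= threshold
}

#' Read a viability screen table
#'
#' Reads a comma-separated screen table with columns `run_id`, `cell_line`,
#' `replicate` and either `viability_pct` (already normalized) or `signal`
#' (raw readout, normalized here against the vehicle run).
#'
#' @param path Path to the CSV file.
#' @param vehicle_run Run identifier of the vehicle (all-drugs-absent)
#'   condition; required when the table carries raw `signal`.
#'
#' @return A tibble of viability records with a `viability_pct` column.
#' @export
read_viability_csv <- function(path, vehicle_run = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("run_id", "cell_line", "replicate")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Viability table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tgmo_validation_error")
  }
  if (!"viability_pct" %in% names(x)) {
    if (!"signal" %in% names(x)) {
      abort("Viability table needs either 'viability_pct' or 'signal'.",
            class = "tgmo_validation_error")
    }
    if (is.null(vehicle_run)) {
      abort("Raw-signal tables require 'vehicle_run' for normalization.",
            class = "tgmo_validation_error")
    }
    x <- normalize_screen(x, vehicle_run = vehicle_run)
  }
  validate_viability(x)
  x
}

#' Normalize a raw-signal screen table to its vehicle run
#'
#' Each (cell line, replicate) is treated as one plate/experiment: its wells
#' are normalized against the mean vehicle-run signal of that same plate.
#'
#' @param data Tibble with columns `run_id`, `cell_line`, `replicate`,
#'   `signal`.
#' @param vehicle_run Run identifier of the vehicle condition.
#'
#' @return The input tibble with a `viability_pct` column added.
#' @export
normalize_screen <- function(data, vehicle_run) {
  if (!vehicle_run %in% data$run_id) {
    abort(paste0("Vehicle run '", vehicle_run, "' absent from the table."),
          class = "tgmo_normalization_error")
  }
  data |>
    dplyr::group_by(.data$cell_line, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      veh <- d$signal[d$run_id == vehicle_run]
      plate <- paste(key$cell_line, key$replicate, sep = "/")
      d$viability_pct <- normalize_to_vehicle(d$signal, veh, plate = plate)
      d
    }) |>
    dplyr::ungroup()
}

validate_viability <- function(data) {
  if (any(data$viability_pct < 0, na.rm = TRUE)) {
    abort("Negative viability after normalization.",
          class = "tgmo_validation_error")
  }
  if (any(data$replicate < 1)) {
    abort("Replicate indices must be >= 1.", class = "tgmo_validation_error")
  }
  invisible(data)
}

#' Summarise a screen per run and cell line
#'
#' @param data Tibble of viability records (`run_id`, `cell_line`,
#'   `replicate`, `viability_pct`).
#'
#' @return Tibble with one row per (run, line): `mean`, `sd`, `n`.
#' @export
summarise_screen <- function(data) {
  data |>
    dplyr::group_by(.data$run_id, .data$cell_line) |>
    dplyr::summarise(
      mean = mean(.data$viability_pct),
      sd = ifelse(dplyr::n() > 1, sd(.data$viability_pct), NA_real_),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Write the per-run screen summary to CSV
#'
#' @param data Tibble of viability records.
#' @param path Output CSV path.
#' @return The summary tibble, invisibly.
#' @export
write_screen_normalized <- function(data, path) {
  out <- summarise_screen(data)
  readr::write_csv(out, path)
  invisible(out)
}

#' Read a drug table
#'
#' Expects columns `drug`, `cud_uM` (clinically used dose) and optionally
#' `screen_dose_uM`; all doses in micromolar.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_drugs_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("drug", "cud_uM") %in% names(x))) {
    abort("Drug table needs columns 'drug' and 'cud_uM'.",
          class = "tgmo_validation_error")
  }
  x
}
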