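#' Per-trial wind-tunnel assay records
#'
#' A trial records one female mosquito released into the wind tunnel and
#' followed for up to 60 minutes. The trial ends in one of three outcomes:
#' `SUCCESS` (the mosquito passed through the 1 cm hole in the net),
#' `FAIL_ALIVE` (still in the release chamber, alive) or `FAIL_KD`
#' (knocked down: lying on its side or back with no tarsal contact with the
#' floor). Knock-down only occurs on insecticide-treated nets; trials on the
#' untreated net (`UTN`) never carry the `FAIL_KD` outcome.
#'
#' A trial table is an ordinary tibble with columns
#' \describe{
#'   \item{trial_id}{opaque identifier (character)}
#'   \item{genotype}{`"SS"`, `"RS"` or `"RR"` at the Kdr locus}
#'   \item{treatment}{`"UTN"`, `"OLYSET"` or `"PERMANET"`}
#'   \item{outcome}{`"SUCCESS"`, `"FAIL_ALIVE"` or `"FAIL_KD"`}
#'   \item{duration_s}{observed duration in seconds; equal to the time to
#'     pass for successes and 3600 s (the full assay) for failures}
#'   \item{n_net_contacts, flight_time_s, time_on_net_s, time_on_walls_s,
#'     mean_speed, time_to_pass_s}{optional video-derived behavioral traits;
#'     missing values allowed}
#' }
#'
#' @name trial-data
NULL

# prose aliases accepted on ingestion, mapped to canonical tokens
GENOTYPE_ALIASES <- c(
  "SS" = "SS", "RS" = "RS", "SR" = "RS", "RR" = "RR",
  "KDR-SS" = "SS", "KDR-RS" = "RS", "KDR-RR" = "RR"
)
TREATMENT_ALIASES <- c(
  "UTN" = "UTN", "UNTREATED" = "UTN", "UNTREATED NET" = "UTN",
  "CONTROL" = "UTN",
  "OLYSET" = "OLYSET", "OLYSET NET" = "OLYSET", "PERMETHRIN" = "OLYSET",
  "PERMANET" = "PERMANET", "PERMANET 2.0" = "PERMANET",
  "DELTAMETHRIN" = "PERMANET"
)
OUTCOME_ALIASES <- c(
  "SUCCESS" = "SUCCESS", "SUCCESSFUL" = "SUCCESS", "PASSED" = "SUCCESS",
  "FAIL_ALIVE" = "FAIL_ALIVE", "UNSUCCESSFUL ALIVE" = "FAIL_ALIVE",
  "ALIVE" = "FAIL_ALIVE",
  "FAIL_KD" = "FAIL_KD", "UNSUCCESSFUL KD" = "FAIL_KD", "KD" = "FAIL_KD",
  "KNOCKED DOWN" = "FAIL_KD", "KNOCK-DOWN" = "FAIL_KD"
)

TRAIT_COLUMNS <- c(
  "n_net_contacts", "flight_time_s", "time_on_net_s", "time_on_walls_s",
  "mean_speed", "time_to_pass_s"
)

ASSAY_DURATION_S <- 3600

map_tokens <- function(x, aliases, what, rows) {
  key <- toupper(trimws(as.character(x)))
  out <- unname(aliases[key])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown %s token '%s' in row %d", what, x[bad[1]], rows[bad[1]]
    ), call. = FALSE)
  }
  out
}

#' Validate a table of trial records
#'
#' Checks the structural invariants of the assay: canonical tokens; duration
#' in (0, 3600] seconds; failures observed for the full 3600 s assay;
#' successes with `duration_s` equal to `time_to_pass_s` when both are
#' present; behavioral time budgets not exceeding the observed duration; and
#' no knock-down outcome on the untreated net.
#'
#' @param trials tibble of trial records (see [trial-data]).
#' @return the input, invisibly, if valid; otherwise an error naming the
#'   violated rule and the first offending row.
#' @export
validate_trials <- function(trials) {
  required <- c("trial_id", "genotype", "treatment", "outcome", "duration_s")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- seq_len(nrow(trials))
  fail_rule <- function(cond, rule) {
    bad <- which(cond)
    if (length(bad) > 0) {
      stop(sprintf("invalid trial (row %d): %s", bad[1], rule), call. = FALSE)
    }
  }
  fail_rule(!trials$genotype %in% GENOTYPES, "genotype not one of SS/RS/RR")
  fail_rule(!trials$treatment %in% TREATMENTS,
            "treatment not one of UTN/OLYSET/PERMANET")
  fail_rule(!trials$outcome %in% OUTCOMES,
            "outcome not one of SUCCESS/FAIL_ALIVE/FAIL_KD")
  fail_rule(!is.finite(trials$duration_s) | trials$duration_s <= 0 |
              trials$duration_s > ASSAY_DURATION_S,
            "duration_s must lie in (0, 3600] seconds")
  fail_rule(trials$outcome != "SUCCESS" &
              trials$duration_s != ASSAY_DURATION_S,
            "failed trials must be observed for the full 3600 s assay")
  fail_rule(trials$treatment == "UTN" & trials$outcome == "FAIL_KD",
            "knock-down cannot occur on the untreated net (UTN)")
  if ("time_to_pass_s" %in% names(trials)) {
    ttp <- trials$time_to_pass_s
    fail_rule(!is.na(ttp) & trials$outcome != "SUCCESS",
              "time_to_pass_s is only defined for successful trials")
    fail_rule(trials$outcome == "SUCCESS" & !is.na(ttp) &
                abs(ttp - trials$duration_s) > 1e-6,
              "for successes duration_s must equal time_to_pass_s")
  }
  budget_cols <- c("flight_time_s", "time_on_net_s", "time_on_walls_s")
  if (all(budget_cols %in% names(trials))) {
    budget <- rowSums(as.matrix(trials[budget_cols]))
    fail_rule(!is.na(budget) & budget > trials$duration_s + 1e-6,
              "flight + net + wall time exceeds observed duration")
  }
  for (col in intersect(c("n_net_contacts", budget_cols), names(trials))) {
    fail_rule(!is.na(trials[[col]]) & trials[[col]] < 0,
              sprintf("%s must be nonnegative", col))
  }
  if ("mean_speed" %in% names(trials)) {
    fail_rule(!is.na(trials$mean_speed) & trials$mean_speed <= 0,
              "mean_speed must be positive")
  }
  invisible(trials)
}

#' Read trial records from CSV
#'
#' Reads a comma-separated, UTF-8 file with one header row. Header matching
#' is case-insensitive, genotype/treatment/outcome values are mapped through
#' a documented alias table (e.g. `"PermaNet 2.0"` to `"PERMANET"`), and the
#' resulting table is validated with [validate_trials()]. Missing optional
#' traits are encoded as empty fields.
#'
#' @param path path to a CSV file of trial records.
#' @return a validated tibble of trial records.
#' @export
read_trials <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         name_repair = "minimal")
  names(raw) <- tolower(names(raw))
  required <- c("trial_id", "genotype", "treatment", "outcome", "duration_s")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- seq_len(nrow(raw))
  trials <- tibble::tibble(
    trial_id = as.character(raw$trial_id),
    genotype = map_tokens(raw$genotype, GENOTYPE_ALIASES, "genotype", rows),
    treatment = map_tokens(raw$treatment, TREATMENT_ALIASES, "treatment",
                           rows),
    outcome = map_tokens(raw$outcome, OUTCOME_ALIASES, "outcome", rows),
    duration_s = as.numeric(raw$duration_s)
  )
  for (col in TRAIT_COLUMNS) {
    if (col %in% names(raw)) trials[[col]] <- as.numeric(raw[[col]])
  }
  validate_trials(trials)
  trials
}

#' Write trial records to CSV
#'
#' @param trials validated trial tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' Tabulate trial outcomes by genotype and treatment
#'
#' Aggregates per-trial records into the genotype x treatment outcome count
#' table used by all downstream models. All 9 genotype x treatment cells are
#' present in the output (zero counts for unobserved cells), so the result
#' of an empty input is the zero table. The operation is invariant to the
#' order of the input rows and conserves the trial count.
#'
#' @param trials validated trial tibble.
#' @return tibble with columns `genotype`, `treatment`, `n_success`,
#'   `n_fail_alive`, `n_fail_kd`, `n_total`.
#' @export
tabulate_outcomes <- function(trials) {
  validate_trials(trials)
  grid <- tidyr::expand_grid(
    genotype = GENOTYPES,
    treatment = TREATMENTS
  )
  counts <- trials |>
    dplyr::count(.data$genotype, .data$treatment, .data$outcome) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L)
  for (col in OUTCOMES) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  grid |>
    dplyr::left_join(counts, by = c("genotype", "treatment")) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(OUTCOMES),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::transmute(
      genotype = .data$genotype,
      treatment = .data$treatment,
      n_success = as.integer(.data$SUCCESS),
      n_fail_alive = as.integer(.data$FAIL_ALIVE),
      n_fail_kd = as.integer(.data$FAIL_KD),
      n_total = .data$n_success + .data$n_fail_alive + .data$n_fail_kd
    )
}

#' Validate an outcome count table
#'
#' @param table tibble with columns `genotype`, `treatment`, `n_success`,
#'   `n_fail_alive`, `n_fail_kd` (and optionally `n_total`, recomputed).
#' @return the table with `n_total` recomputed, rows in canonical order.
#' @export
as_outcome_table <- function(table) {
  required <- c("genotype", "treatment", "n_success", "n_fail_alive",
                "n_fail_kd")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!table$genotype %in% GENOTYPES)) stop("unknown genotype token")
  if (any(!table$treatment %in% TREATMENTS)) stop("unknown treatment token")
  counts <- as.matrix(table[c("n_success", "n_fail_alive", "n_fail_kd")])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(table$treatment == "UTN" & table$n_fail_kd > 0)) {
    stop("UTN cells cannot have knock-down counts")
  }
  if (anyDuplicated(table[c("genotype", "treatment")]) > 0) {
    stop("duplicated genotype x treatment cell")
  }
  table |>
    dplyr::mutate(
      n_total = .data$n_success + .data$n_fail_alive + .data$n_fail_kd
    ) |>
    dplyr::arrange(match(.data$treatment, TREATMENTS),
                   match(.data$genotype, GENOTYPES))
}

#' Read / write an outcome count table
#'
#' CSV with columns `genotype`, `treatment`, `n_success`, `n_fail_alive`,
#' `n_fail_kd`. `write_outcome_table()` and `read_outcome_table()` round-trip
#' losslessly.
#'
#' @param path CSV path.
#' @return `read_outcome_table()`: a validated outcome table tibble.
#' @export
read_outcome_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  raw$genotype <- map_tokens(raw$genotype, GENOTYPE_ALIASES, "genotype",
                             seq_len(nrow(raw)))
  raw$treatment <- map_tokens(raw$treatment, TREATMENT_ALIASES, "treatment",
                              seq_len(nrow(raw)))
  as_outcome_table(raw)
}

#' @rdname read_outcome_table
#' @param table outcome table tibble.
#' @return `write_outcome_table()`: `path`, invisibly.
#' @export
write_outcome_table <- function(table, path) {
  table <- as_outcome_table(table)
  readr::write_csv(
    table[c("genotype", "treatment", "n_success", "n_fail_alive",
            "n_fail_kd")],
    path
  )
  invisible(path)
}
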