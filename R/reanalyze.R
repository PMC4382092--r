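#' Run the full outcome analysis on one dataset
#'
#' Chains every analysis stage: tabulation (if trial-level input),
#' proportion confidence intervals, pairwise success odds ratios from the
#' saturated binomial model, knock-down contrasts from the multinomial
#' model, Monte-Carlo profile-likelihood fitness inference per treatment,
#' and (when trial-level behavioral traits are present) the behavioral
#' comparisons. Results come back as a list of tidy tibbles; when `out_dir`
#' is given they are also written as CSV files together with a JSON run
#' manifest (command, seed, configuration snapshot, input digest, package
#' version, timestamp).
#'
#' @param trials trial tibble (or `NULL` when `table` is given).
#' @param table outcome table (ignored when `trials` is given).
#' @param n_draws Monte-Carlo draws per treatment for fitness inference.
#' @param seed integer seed used for the profile draws.
#' @param level confidence level used throughout.
#' @param out_dir optional output directory for the report bundle.
#' @return object of class `kdr_report`: list with `table`, `proportions`,
#'   `success_or`, `kd_contrasts`, `fitness`, `behavior`, `manifest`.
#' @export
reanalyze <- function(trials = NULL, table = NULL, n_draws = 100000,
                      seed = 1, level = 0.95, out_dir = NULL) {
  if (is.null(trials) && is.null(table)) {
    stop("provide trial-level data or an outcome table", call. = FALSE)
  }
  if (!is.null(trials)) {
    validate_trials(trials)
    table <- tabulate_outcomes(trials)
  } else {
    table <- as_outcome_table(table)
  }
  proportions <- outcome_proportions(table, level = level)
  success_or <- pairwise_odds_ratios(table, level = level)
  treated <- table[table$treatment != "UTN", ]
  kd_contrasts <- NULL
  if (nrow(treated[treated$n_total > 0, ]) > 0 &&
      sum(treated$n_fail_alive) > 0 && sum(treated$n_fail_kd) > 0) {
    kd_contrasts <- kd_treatment_contrasts(table, level = level)
  }
  fitness <- purrr::map_dfr(
    intersect(TREATMENTS, unique(table$treatment[table$n_total > 0])),
    function(t) {
      cells <- table[table$treatment == t, ]
      if (!all(GENOTYPES %in% cells$genotype[cells$n_total > 0])) {
        return(NULL)
      }
      fit <- estimate_fitness(table, t, n_draws = n_draws, seed = seed,
                              level = level)
      fit$estimates
    }
  )
  behavior <- NULL
  if (!is.null(trials) && "n_net_contacts" %in% names(trials) &&
      any(trials$treatment == "UTN")) {
    utn <- trials[trials$treatment == "UTN", ]
    if (!anyNA(utn$n_net_contacts) &&
        length(unique(utn$genotype)) >= 2) {
      behavior <- behavior_summary(trials, treatment = "UTN")
    } else {
      message("behavior section skipped: behavioral traits incomplete")
    }
  } else if (!is.null(trials)) {
    message("behavior section skipped: behavioral traits absent")
  }
  manifest <- list(
    command = "reanalyze",
    seed = seed,
    n_draws = n_draws,
    level = level,
    input = list(
      kind = if (!is.null(trials)) "trials" else "table",
      n_rows = if (!is.null(trials)) nrow(trials) else nrow(table),
      n_trials = sum(table$n_total),
      digest = sum(as.numeric(table$n_success) * seq_len(nrow(table))) +
        sum(as.numeric(table$n_fail_kd))
    ),
    package_version = as.character(utils::packageVersion("kdrfitness")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  report <- structure(
    list(table = table, proportions = proportions,
         success_or = success_or, kd_contrasts = kd_contrasts,
         fitness = fitness, behavior = behavior, manifest = manifest),
    class = "kdr_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_outcome_table(report$table, file.path(out_dir, "outcome_table.csv"))
  readr::write_csv(report$proportions,
                   file.path(out_dir, "proportions.csv"))
  readr::write_csv(report$success_or,
                   file.path(out_dir, "success_odds_ratios.csv"))
  if (!is.null(report$kd_contrasts)) {
    readr::write_csv(report$kd_contrasts,
                     file.path(out_dir, "kd_contrasts.csv"))
  }
  if (nrow(report$fitness) > 0) {
    readr::write_csv(report$fitness, file.path(out_dir, "fitness.csv"))
  }
  if (!is.null(report$behavior)) {
    if (!is.null(report$behavior$contact_rates)) {
      readr::write_csv(report$behavior$contact_rates,
                       file.path(out_dir, "behavior_contact_rates.csv"))
    }
    if (nrow(report$behavior$rank_tests) > 0) {
      readr::write_csv(
        tidyr::unnest(report$behavior$rank_tests, "dunn",
                      names_sep = "_"),
        file.path(out_dir, "behavior_rank_tests.csv"))
    }
  }
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.kdr_report <- function(x, ...) {
  tab <- x$table
  n <- sum(tab$n_total)
  k <- sum(tab$n_success)
  overall <- wilson_ci(k, n, continuity = FALSE)
  cat("== Wind-tunnel outcome reanalysis ==\n")
  cat(sprintf("overall success rate = %.1f%% (N = %d/%d) [%.1f-%.1f]\n",
              100 * k / n, k, n, 100 * overall$lower, 100 * overall$upper))
  cat("\n-- success proportions (Wilson) --\n")
  print(dplyr::filter(x$proportions, .data$measure == "success"), n = 12)
  cat("\n-- pairwise success odds ratios --\n")
  print(x$success_or, n = 30)
  if (!is.null(x$kd_contrasts)) {
    cat("\n-- knock-down vs alive, between nets (multinomial) --\n")
    print(x$kd_contrasts)
  }
  if (nrow(x$fitness) > 0) {
    cat("\n-- selection and dominance --\n")
    print(dplyr::select(x$fitness, "treatment", "s", "s_lower", "s_upper",
                        "h", "h_lower", "h_upper",
                        "h_upper_unbounded"))
  }
  if (!is.null(x$behavior)) {
    cat("\n-- behavioral traits (UTN) --\n")
    if (!is.null(x$behavior$contact_rates)) {
      print(x$behavior$contact_rates)
    }
    if (nrow(x$behavior$rank_tests) > 0) {
      print(dplyr::select(x$behavior$rank_tests, -"dunn"))
    }
  }
  invisible(x)
}
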