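#' Poisson contact-rate model with duration offset
#'
#' Net-contact counts are modeled as Poisson with a log link and
#' `log(duration)` offset, so genotype coefficients are log contact-rate
#' ratios (CRR) per unit time. Durations enter as observed: time to pass for
#' successful trials, the full 3600 s for failures. All pairwise genotype
#' CRRs are returned with Wald intervals.
#'
#' @param trials trial tibble with `n_net_contacts` and `duration_s`
#'   present.
#' @param treatment restrict to one treatment (default `"UTN"`, where the
#'   video traits were scored); `NULL` uses all rows.
#' @param level confidence level.
#' @return tibble with columns `contrast` (e.g. `"RR-vs-SS"`, first level in
#'   the numerator), `crr`, `conf.low`, `conf.high`, `p.value`.
#' @export
contact_rate_model <- function(trials, treatment = "UTN", level = 0.95) {
  validate_trials(trials)
  if (!is.null(treatment)) {
    trials <- trials[trials$treatment == treatment, ]
  }
  if (!"n_net_contacts" %in% names(trials) ||
      anyNA(trials$n_net_contacts)) {
    stop("n_net_contacts must be present for all trials", call. = FALSE)
  }
  gs <- intersect(GENOTYPES, unique(trials$genotype))
  if (length(gs) < 2) stop("need >= 2 genotypes", call. = FALSE)
  dat <- data.frame(
    y = trials$n_net_contacts,
    genotype = factor(trials$genotype, levels = gs),
    log_dur = log(trials$duration_s)
  )
  # genotypes with zero total counts make the log-rate diverge; +0.5 to one
  # count in the affected genotype keeps the contrast finite, flagged
  zero_gs <- gs[vapply(gs, function(g) sum(dat$y[dat$genotype == g]) == 0,
                       logical(1))]
  corrected <- length(zero_gs) > 0
  if (corrected) {
    for (g in zero_gs) {
      i <- which(dat$genotype == g)[1]
      dat$y[i] <- dat$y[i] + 0.5
    }
  }
  fit_call <- quote(glm(y ~ genotype + offset(log_dur), family = poisson(),
                        data = dat,
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 100)))
  # the +0.5 correction makes one count non-integer; the dpois warning about
  # it is expected there
  fit <- if (corrected) suppressWarnings(eval(fit_call)) else eval(fit_call)
  beta <- coef(fit)
  vc <- vcov(fit)
  z <- qnorm(1 - (1 - level) / 2)
  rows <- purrr::map_dfr(utils::combn(gs, 2, simplify = FALSE),
                         function(pair) {
    cv <- setNames(numeric(length(beta)), names(beta))
    term <- function(g) paste0("genotype", g)
    # log CRR of pair[2] vs pair[1] reference, we report pair[2]-vs-pair[1]
    if (term(pair[2]) %in% names(cv)) cv[term(pair[2])] <- 1
    if (term(pair[1]) %in% names(cv)) cv[term(pair[1])] <- -1
    log_crr <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% vc %*% cv))
    tibble::tibble(
      contrast = paste0(pair[2], "-vs-", pair[1]),
      crr = exp(log_crr),
      conf.low = exp(log_crr - z * se),
      conf.high = exp(log_crr + z * se),
      p.value = 2 * pnorm(-abs(log_crr / se)),
      corrected = corrected
    )
  })
  rows
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on (number of groups - 1) degrees of freedom.
#'
#' @param x numeric response values.
#' @param g group labels (coerced to factor).
#' @return object of class `kdr_ranktest`: `statistic` (H), `df`, `p.value`,
#'   `n` per group.
#' @export
kruskal_wallis <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 1)) stop("every group needs >= 1 value", call. = FALSE)
  if (length(unique(x)) == 1) {
    # one big tie group: no rank variation, H = 0 by convention
    return(structure(
      list(statistic = 0, df = nlevels(g) - 1L, p.value = 1,
           n = as.integer(table(g)), groups = levels(g)),
      class = "kdr_ranktest"
    ))
  }
  kt <- kruskal.test(x, g)
  structure(
    list(
      statistic = unname(kt$statistic),
      df = unname(kt$parameter),
      p.value = kt$p.value,
      n = as.integer(table(g)),
      groups = levels(g)
    ),
    class = "kdr_ranktest"
  )
}

#' @export
print.kdr_ranktest <- function(x, ...) {
  cat("Kruskal-Wallis rank sum test (tie-corrected)\n")
  cat(sprintf("  H = %.4f, df = %d, p = %.4g\n", x$statistic, x$df,
              x$p.value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kdr_ranktest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' Dunn's post-hoc pairwise rank comparisons
#'
#' Pairwise z statistics on mean ranks of the pooled sample with the tie
#' correction, following a Kruskal-Wallis test. For two groups, z^2 equals
#' the Kruskal-Wallis H.
#'
#' @param x numeric response values.
#' @param g group labels.
#' @param adjustment multiplicity adjustment across the pairwise
#'   comparisons: `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return tibble with `contrast`, `z`, `p.value` (raw two-sided normal) and
#'   `p.adjusted`.
#' @export
dunn_posthoc <- function(x, g, adjustment = c("bonferroni", "holm",
                                              "none")) {
  adjustment <- match.arg(adjustment)
  g <- factor(g)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_term
  mean_ranks <- tapply(r, g, mean)
  sizes <- table(g)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pair) {
    se <- sqrt(var_base * (1 / sizes[[pair[1]]] + 1 / sizes[[pair[2]]]))
    z <- if (se == 0) 0 else
      (mean_ranks[[pair[1]]] - mean_ranks[[pair[2]]]) / se
    tibble::tibble(
      contrast = paste0(pair[1], "-vs-", pair[2]),
      z = z,
      p.value = 2 * pnorm(-abs(z))
    )
  })
  res$p.adjusted <- p.adjust(res$p.value, method =
                               if (adjustment == "none") "none"
                             else adjustment)
  res
}

#' Behavioral trait comparisons among genotypes
#'
#' Runs the per-variable analyses on trial-level data: the Poisson
#' contact-rate model for net contacts, and Kruskal-Wallis with Dunn
#' post-hoc tests for the proportion of time flying, mean flight speed,
#' proportions of time on the net and on the walls, and (successful trials
#' only) the time to pass through the hole. Traits absent from the input are
#' skipped.
#'
#' @param trials trial tibble.
#' @param treatment treatment to analyze (default `"UTN"`).
#' @param adjustment Dunn adjustment method.
#' @return list with elements `contact_rates` (tibble or `NULL`) and
#'   `rank_tests` (tibble: `variable`, `H`, `df`, `p.value`, plus nested
#'   `dunn` tibbles).
#' @export
behavior_summary <- function(trials, treatment = "UTN",
                             adjustment = "bonferroni") {
  validate_trials(trials)
  sub <- trials[trials$treatment == treatment, ]
  contact <- NULL
  if ("n_net_contacts" %in% names(sub) && !anyNA(sub$n_net_contacts)) {
    contact <- contact_rate_model(sub, treatment = NULL)
  }
  # rank-test variables: value extractor per variable
  vars <- list(
    flight_time_fraction = function(d) d$flight_time_s / d$duration_s,
    mean_speed = function(d) d$mean_speed,
    time_on_net_fraction = function(d) d$time_on_net_s / d$duration_s,
    time_on_walls_fraction = function(d) d$time_on_walls_s / d$duration_s,
    time_to_pass_s = function(d) {
      ok <- d$outcome == "SUCCESS"
      out <- rep(NA_real_, nrow(d))
      out[ok] <- d$time_to_pass_s[ok]
      out
    }
  )
  needed <- c(flight_time_fraction = "flight_time_s",
              mean_speed = "mean_speed",
              time_on_net_fraction = "time_on_net_s",
              time_on_walls_fraction = "time_on_walls_s",
              time_to_pass_s = "time_to_pass_s")
  rank_tests <- purrr::imap_dfr(vars, function(f, nm) {
    if (!needed[[nm]] %in% names(sub)) return(NULL)
    vals <- f(sub)
    keep <- !is.na(vals)
    if (sum(keep) < 3 || length(unique(sub$genotype[keep])) < 2) {
      return(NULL)
    }
    kw <- kruskal_wallis(vals[keep], sub$genotype[keep])
    dunn <- dunn_posthoc(vals[keep], sub$genotype[keep], adjustment)
    tibble::tibble(
      variable = nm, H = kw$statistic, df = kw$df, p.value = kw$p.value,
      dunn = list(dunn)
    )
  })
  list(contact_rates = contact, rank_tests = rank_tests)
}
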