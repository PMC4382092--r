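#' Relative fitness of Kdr genotypes from success proportions
#'
#' Uses the proportion of mosquitoes successfully passing through the holed
#' net as a proxy for relative fitness: `w_i = p_i / p_SS`, so `w_SS = 1` by
#' construction.
#'
#' @param table outcome table.
#' @param treatment treatment to evaluate (`"UTN"`, `"OLYSET"` or
#'   `"PERMANET"`).
#' @return one-row tibble: `treatment`, `p_SS`, `p_RS`, `p_RR`, `w_RS`,
#'   `w_RR`.
#' @export
#' @examples
#' relative_fitness(kdr_assay_counts(), "UTN")
relative_fitness <- function(table, treatment) {
  table <- as_outcome_table(table)
  cells <- table[table$treatment == treatment, ]
  if (nrow(cells) == 0) stop("treatment absent from table", call. = FALSE)
  p_of <- function(g) {
    cell <- cells[cells$genotype == g, ]
    if (nrow(cell) == 0 || cell$n_total == 0) {
      stop(sprintf("no trials for genotype %s under %s", g, treatment),
           call. = FALSE)
    }
    cell$n_success / cell$n_total
  }
  p <- vapply(GENOTYPES, p_of, numeric(1))
  if (p[["SS"]] == 0) {
    stop("relative fitness undefined: p_SS = 0", call. = FALSE)
  }
  tibble::tibble(
    treatment = treatment,
    p_SS = p[["SS"]], p_RS = p[["RS"]], p_RR = p[["RR"]],
    w_RS = p[["RS"]] / p[["SS"]],
    w_RR = p[["RR"]] / p[["SS"]]
  )
}

#' Decompose relative fitnesses into selection and dominance coefficients
#'
#' Under the single-locus parameterization `w_SS = 1`, `w_RS = 1 + h s`,
#' `w_RR = 1 + s`: the selection coefficient is `s = w_RR - 1` and the
#' dominance coefficient is `h = (w_RS - 1) / s`. `h` is undefined (returned
#' as `NA` with `h_defined = FALSE`) when `|s|` is numerically zero, since
#' any `h` then fits.
#'
#' @param w_RS,w_RR relative fitnesses of the heterozygote and the resistant
#'   homozygote (vectorized).
#' @return tibble with columns `w_RS`, `w_RR`, `s`, `h`, `h_defined`.
#' @export
#' @examples
#' decompose_fitness(w_RS = 0.975, w_RR = 0.6375)
decompose_fitness <- function(w_RS, w_RR) {
  s <- w_RR - 1
  defined <- abs(s) >= 1e-12
  h <- ifelse(defined, (w_RS - 1) / s, NA_real_)
  tibble::tibble(w_RS = w_RS, w_RR = w_RR, s = s, h = h,
                 h_defined = defined)
}

# clamp logit of k/n, flagging degenerate cells
clamped_logit <- function(k, n, clamp = 12) {
  p <- k / n
  if (k == 0) list(a = -clamp, clamped = TRUE)
  else if (k == n) list(a = clamp, clamped = TRUE)
  else list(a = qlogis(p), clamped = FALSE)
}

# log-likelihood of three independent binomial cells at given logits
cell_loglik <- function(a_SS, a_RS, a_RR, k, n) {
  dbinom(k[["SS"]], n[["SS"]], plogis(a_SS), log = TRUE) +
    dbinom(k[["RS"]], n[["RS"]], plogis(a_RS), log = TRUE) +
    dbinom(k[["RR"]], n[["RR"]], plogis(a_RR), log = TRUE)
}

# bin an envelope: per-bin maximum of ll over values of x falling in
# equal-width bins spanning range; returns tibble plus overflow maxima
bin_envelope <- function(x, ll, range, n_bins) {
  width <- (range[2] - range[1]) / n_bins
  idx <- floor((x - range[1]) / width) + 1
  inside <- which(idx >= 1 & idx <= n_bins & is.finite(x))
  env <- rep(NA_real_, n_bins)
  if (length(inside) > 0) {
    agg <- tapply(ll[inside], idx[inside], max)
    env[as.integer(names(agg))] <- as.numeric(agg)
  }
  over_lo <- suppressWarnings(max(ll[is.finite(x) & x < range[1]]))
  over_hi <- suppressWarnings(max(ll[is.finite(x) & x > range[2]]))
  list(
    curve = tibble::tibble(
      bin = seq_len(n_bins),
      mid = range[1] + (seq_len(n_bins) - 0.5) * width,
      lower = range[1] + (seq_len(n_bins) - 1) * width,
      upper = range[1] + seq_len(n_bins) * width,
      max_ll = env
    ),
    width = width,
    overflow = c(lower = over_lo, upper = over_hi)
  )
}

#' Monte-Carlo cloud profile likelihood for selection and dominance
#'
#' The success probabilities of the three genotypes under one treatment are
#' modeled as independent binomials with logits `a_SS`, `a_RS`, `a_RR`.
#' Selection (`s`) and dominance (`h`) are functions of the three logits, so
#' their profile likelihoods are obtained by sampling `(a_RS, a_RR)` pairs
#' uniformly over a box, profiling out `a_SS`, and taking the upper envelope
#' of attained log-likelihood against the implied `h` or `s`.
#'
#' Because the three binomial likelihoods are separable, the conditional
#' maximizer of `a_SS` does not depend on the sampled pair and equals
#' `logit(k_SS / n_SS)` (clamped for degenerate cells and flagged); a
#' numerical 1-D maximization path is retained behind `profile_a_ss =
#' "numeric"` for fidelity checks. The analytic maximum-likelihood point is
#' appended to the cloud so the envelope always attains the saturated
#' maximum at the MLE.
#'
#' @param table outcome table.
#' @param treatment treatment to analyze.
#' @param n_draws number of `(a_RS, a_RR)` pairs (default 100,000).
#' @param box uniform sampling bounds in logit units: the default `NULL`
#'   centers each coefficient's box on its maximum-likelihood value with
#'   half-width `max(6 SE, 1.5)` (clipped to \[-12, 12\]), which keeps the
#'   cloud dense where the likelihood is non-negligible; a length-2 numeric
#'   imposes one fixed box on both coefficients instead.
#' @param s_range,h_range envelope ranges for the binned profile curves.
#' @param s_bins,h_bins number of equal-width envelope bins.
#' @param seed integer seed for the draws (recorded in the result).
#' @param profile_a_ss `"closed_form"` (default) or `"numeric"`.
#' @param keep_draws keep the full cloud in the result (default `TRUE`).
#' @return object of class `kdr_profile`: `draws` (tibble: `a_RS`, `a_RR`,
#'   `a_SS`, `log_lik`, `s`, `h`), `envelope_s`, `envelope_h` (binned
#'   curves), `max_ll`, `mle` (tibble with analytic `s`, `h`), `overflow_s`,
#'   `overflow_h`, `bin_width_s`, `bin_width_h`, `seed`, `box`, `n_draws`,
#'   `ss_clamped`, `treatment`.
#' @export
mc_profile <- function(table, treatment, n_draws = 100000,
                       box = NULL,
                       s_range = c(-1, 1), s_bins = 512,
                       h_range = c(-5, 105), h_bins = 1024,
                       seed = NULL, profile_a_ss = c("closed_form",
                                                     "numeric"),
                       keep_draws = TRUE) {
  profile_a_ss <- match.arg(profile_a_ss)
  table <- as_outcome_table(table)
  cells <- table[table$treatment == treatment, ]
  if (!all(GENOTYPES %in% cells$genotype[cells$n_total > 0])) {
    stop("all three genotype cells must be present for the treatment",
         call. = FALSE)
  }
  k <- setNames(cells$n_success[match(GENOTYPES, cells$genotype)], GENOTYPES)
  n <- setNames(cells$n_total[match(GENOTYPES, cells$genotype)], GENOTYPES)

  ss <- clamped_logit(k[["SS"]], n[["SS"]])
  a_SS_hat <- if (profile_a_ss == "closed_form") ss$a else {
    stats::optimize(
      function(a) dbinom(k[["SS"]], n[["SS"]], plogis(a), log = TRUE),
      interval = c(-12, 12), maximum = TRUE, tol = 1e-10
    )$maximum
  }

  rs_hat <- clamped_logit(k[["RS"]], n[["RS"]])
  rr_hat <- clamped_logit(k[["RR"]], n[["RR"]])
  coef_box <- function(g, a_hat) {
    if (!is.null(box)) return(box)
    p_smooth <- (k[[g]] + 0.5) / (n[[g]] + 1)
    se <- 1 / sqrt(n[[g]] * p_smooth * (1 - p_smooth))
    half <- max(6 * se, 1.5)
    c(max(a_hat - half, -12), min(a_hat + half, 12))
  }
  box_rs <- coef_box("RS", rs_hat$a)
  box_rr <- coef_box("RR", rr_hat$a)

  if (!is.null(seed)) set.seed(seed)
  a_RS <- runif(n_draws, box_rs[1], box_rs[2])
  a_RR <- runif(n_draws, box_rr[1], box_rr[2])
  # append the analytic MLE so the envelope attains the global maximum
  a_RS <- c(a_RS, rs_hat$a)
  a_RR <- c(a_RR, rr_hat$a)

  p_SS <- plogis(a_SS_hat)
  p_RS <- plogis(a_RS)
  p_RR <- plogis(a_RR)
  ll <- dbinom(k[["SS"]], n[["SS"]], p_SS, log = TRUE) +
    dbinom(k[["RS"]], n[["RS"]], p_RS, log = TRUE) +
    dbinom(k[["RR"]], n[["RR"]], p_RR, log = TRUE)
  s <- p_RR / p_SS - 1
  h <- (p_RS / p_SS - 1) / s

  env_s <- bin_envelope(s, ll, s_range, s_bins)
  env_h <- bin_envelope(h, ll, h_range, h_bins)
  max_ll <- max(ll)

  # Deterministic profile probes at the envelope range edges decide whether
  # the likelihood remains non-negligible beyond the binned range (the
  # ">100"-style unbounded sides) without relying on sampling luck. By
  # separability the exact profile for fixed s is closed form; for fixed h
  # it is a 1-D maximization over a_RR, evaluated on a fine grid.
  ll_ss_hat <- dbinom(k[["SS"]], n[["SS"]], p_SS, log = TRUE)
  ll_rs_hat <- dbinom(k[["RS"]], n[["RS"]], k[["RS"]] / n[["RS"]],
                      log = TRUE)
  profile_at_s <- function(s_val) {
    p_rr <- p_SS * (1 + s_val)
    if (p_rr < 0 || p_rr > 1) return(-Inf)
    ll_ss_hat + ll_rs_hat + dbinom(k[["RR"]], n[["RR"]], p_rr, log = TRUE)
  }
  profile_at_h <- function(h_val) {
    a_grid <- seq(-12, 12, length.out = 4001)
    p_rr <- plogis(a_grid)
    s_grid <- p_rr / p_SS - 1
    p_rs <- p_SS * (1 + h_val * s_grid)
    ok <- p_rs >= 0 & p_rs <= 1 & abs(s_grid) > 1e-12
    if (!any(ok)) return(-Inf)
    ll_ss_hat + max(
      dbinom(k[["RR"]], n[["RR"]], p_rr[ok], log = TRUE) +
        dbinom(k[["RS"]], n[["RS"]], p_rs[ok], log = TRUE)
    )
  }
  overflow_s <- c(
    lower = max(env_s$overflow[["lower"]], profile_at_s(s_range[1])),
    upper = max(env_s$overflow[["upper"]], profile_at_s(s_range[2]))
  )
  overflow_h <- c(
    lower = max(env_h$overflow[["lower"]], profile_at_h(h_range[1])),
    upper = max(env_h$overflow[["upper"]], profile_at_h(h_range[2]))
  )

  mle <- dplyr::bind_cols(
    tibble::tibble(treatment = treatment),
    decompose_fitness(w_RS = plogis(rs_hat$a) / p_SS,
                      w_RR = plogis(rr_hat$a) / p_SS)
  )

  structure(
    list(
      draws = if (keep_draws) {
        tibble::tibble(a_RS = a_RS, a_RR = a_RR, a_SS = a_SS_hat,
                       log_lik = ll, s = s, h = h)
      } else NULL,
      envelope_s = env_s$curve, envelope_h = env_h$curve,
      bin_width_s = env_s$width, bin_width_h = env_h$width,
      overflow_s = overflow_s, overflow_h = overflow_h,
      max_ll = max_ll, mle = mle,
      seed = seed, box = list(a_RS = box_rs, a_RR = box_rr),
      n_draws = n_draws,
      s_range = s_range, h_range = h_range,
      ss_clamped = ss$clamped, treatment = treatment,
      counts = tibble::tibble(genotype = GENOTYPES, k = unname(k),
                              n = unname(n))
    ),
    class = "kdr_profile"
  )
}

#' @export
print.kdr_profile <- function(x, ...) {
  cat("Monte-Carlo cloud profile likelihood (", x$treatment, ")\n", sep = "")
  cat(sprintf("draws: %d  a_RS box: [%.2f, %.2f]  a_RR box: [%.2f, %.2f]\n",
              x$n_draws, x$box$a_RS[1], x$box$a_RS[2], x$box$a_RR[1],
              x$box$a_RR[2]))
  cat("seed:", x$seed %||% NA, "\n")
  cat("max log-likelihood:", format(x$max_ll, digits = 8), "\n")
  cat("MLE: s =", format(x$mle$s, digits = 4),
      " h =", format(x$mle$h, digits = 4), "\n")
  invisible(x)
}

#' Likelihood-ratio confidence interval from a profile envelope
#'
#' The interval is the set of parameter values whose envelope log-likelihood
#' stays within `qchisq(level, 1) / 2` (1.9207 log-units at 95%) of the
#' maximum. Endpoints are interpolated linearly in log-likelihood between
#' the outermost bin above the threshold and its neighbor below. If the
#' envelope never crosses the threshold before the edge of the binned range
#' on one side (including mass beyond the range with log-likelihood above
#' the threshold), that side is flagged unbounded and reported at the range
#' edge, mirroring the ">100"-style reporting convention.
#'
#' @param profile a `kdr_profile` from [mc_profile()].
#' @param parameter `"s"` or `"h"`.
#' @param level confidence level.
#' @return one-row tibble: `parameter`, `estimate`, `lower`, `upper`,
#'   `lower_unbounded`, `upper_unbounded`, `level`.
#' @export
lr_ci <- function(profile, parameter = c("s", "h"), level = 0.95) {
  stopifnot(inherits(profile, "kdr_profile"))
  parameter <- match.arg(parameter)
  env <- if (parameter == "s") profile$envelope_s else profile$envelope_h
  overflow <- if (parameter == "s") profile$overflow_s else
    profile$overflow_h
  estimate <- profile$mle[[parameter]]
  occupied <- which(!is.na(env$max_ll))
  if (length(occupied) < 3) {
    stop("profile envelope resolution too low: fewer than 3 occupied bins",
         call. = FALSE)
  }
  thr <- profile$max_ll - qchisq(level, df = 1) / 2
  above <- occupied[env$max_ll[occupied] >= thr]
  if (length(above) == 0) {
    stop("no envelope bin reaches the likelihood-ratio threshold",
         call. = FALSE)
  }
  interp <- function(i_above, i_below) {
    # linear interpolation of the crossing point between two bin midpoints
    x1 <- env$mid[i_above]; y1 <- env$max_ll[i_above]
    x0 <- env$mid[i_below]; y0 <- env$max_ll[i_below]
    x1 + (thr - y1) * (x0 - x1) / (y0 - y1)
  }
  # Endpoints are taken at the outermost above-threshold evidence: Monte-
  # Carlo undershoot can only carve false gaps into the envelope (it is a
  # lower bound of the true profile), so interior dips below the threshold
  # are not treated as crossings.
  lo_bin <- min(above)
  if (is.finite(overflow[["lower"]]) && overflow[["lower"]] >= thr) {
    lower <- env$lower[1]
    lower_unbounded <- TRUE
  } else {
    below_lo <- occupied[occupied < lo_bin]
    if (length(below_lo) > 0) {
      lower <- interp(lo_bin, max(below_lo))
      lower_unbounded <- FALSE
    } else {
      lower <- env$lower[lo_bin]
      lower_unbounded <- lo_bin == 1
    }
  }
  hi_bin <- max(above)
  if (is.finite(overflow[["upper"]]) && overflow[["upper"]] >= thr) {
    upper <- env$upper[nrow(env)]
    upper_unbounded <- TRUE
  } else {
    above_hi <- occupied[occupied > hi_bin]
    if (length(above_hi) > 0) {
      upper <- interp(hi_bin, min(above_hi))
      upper_unbounded <- FALSE
    } else {
      upper <- env$upper[hi_bin]
      upper_unbounded <- hi_bin == nrow(env)
    }
  }
  tibble::tibble(
    parameter = parameter, estimate = estimate,
    lower = lower, upper = upper,
    lower_unbounded = lower_unbounded, upper_unbounded = upper_unbounded,
    level = level
  )
}

#' Estimate selection and dominance of the resistance allele
#'
#' End-to-end fitness inference for one treatment: point estimates of the
#' relative fitnesses, their decomposition into `(s, h)`, and
#' likelihood-ratio confidence intervals from the Monte-Carlo cloud profile
#' likelihood.
#'
#' @inheritParams mc_profile
#' @param level confidence level for the likelihood-ratio intervals.
#' @param ... passed on to [mc_profile()].
#' @return object of class `kdr_fitness`: `estimates` (one-row tibble with
#'   `treatment`, `w_RS`, `w_RR`, `s`, `h` and the CI columns
#'   `s_lower`, `s_upper`, `h_lower`, `h_upper` plus unboundedness flags)
#'   and `profile` (the underlying `kdr_profile`).
#' @export
#' @examples
#' \donttest{
#' fit <- estimate_fitness(kdr_assay_counts(), "UTN", n_draws = 20000,
#'                         seed = 1)
#' tidy(fit)
#' }
estimate_fitness <- function(table, treatment, n_draws = 100000,
                             seed = NULL, level = 0.95, ...) {
  w <- relative_fitness(table, treatment)
  point <- decompose_fitness(w$w_RS, w$w_RR)
  profile <- mc_profile(table, treatment, n_draws = n_draws, seed = seed,
                        ...)
  ci_s <- lr_ci(profile, "s", level)
  ci_h <- if (point$h_defined) lr_ci(profile, "h", level) else NULL
  estimates <- tibble::tibble(
    treatment = treatment,
    w_RS = w$w_RS, w_RR = w$w_RR,
    s = point$s, h = point$h, h_defined = point$h_defined,
    s_lower = ci_s$lower, s_upper = ci_s$upper,
    s_lower_unbounded = ci_s$lower_unbounded,
    s_upper_unbounded = ci_s$upper_unbounded,
    h_lower = ci_h$lower %||% NA_real_,
    h_upper = ci_h$upper %||% NA_real_,
    h_lower_unbounded = ci_h$lower_unbounded %||% NA,
    h_upper_unbounded = ci_h$upper_unbounded %||% NA,
    level = level
  )
  structure(list(estimates = estimates, profile = profile),
            class = "kdr_fitness")
}

format_bound <- function(value, unbounded, side, range) {
  if (isTRUE(unbounded)) {
    if (side == "lower") paste0("<", format(range[1], digits = 3))
    else paste0(">", format(range[2], digits = 3))
  } else {
    format(value, digits = 3)
  }
}

#' @export
print.kdr_fitness <- function(x, ...) {
  e <- x$estimates
  p <- x$profile
  cat("Fitness of Kdr genotypes under", e$treatment, "\n")
  cat(sprintf("  w_RS = %.4f, w_RR = %.4f\n", e$w_RS, e$w_RR))
  cat(sprintf("  s = %.3f  [%s, %s]\n", e$s,
              format_bound(e$s_lower, e$s_lower_unbounded, "lower",
                           p$s_range),
              format_bound(e$s_upper, e$s_upper_unbounded, "upper",
                           p$s_range)))
  if (e$h_defined) {
    cat(sprintf("  h = %.3f  [%s, %s]\n", e$h,
                format_bound(e$h_lower, e$h_lower_unbounded, "lower",
                             p$h_range),
                format_bound(e$h_upper, e$h_upper_unbounded, "upper",
                             p$h_range)))
  } else {
    cat("  h undefined (s = 0)\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kdr_fitness <- function(x, ...) {
  e <- x$estimates
  tibble::tibble(
    treatment = e$treatment,
    parameter = c("w_RS", "w_RR", "s", "h"),
    estimate = c(e$w_RS, e$w_RR, e$s, e$h),
    lower = c(NA, NA, e$s_lower, e$h_lower),
    upper = c(NA, NA, e$s_upper, e$h_upper),
    lower_unbounded = c(NA, NA, e$s_lower_unbounded, e$h_lower_unbounded),
    upper_unbounded = c(NA, NA, e$s_upper_unbounded, e$h_upper_unbounded)
  )
}

#' @exportS3Method generics::glance
glance.kdr_fitness <- function(x, ...) {
  tibble::tibble(
    treatment = x$estimates$treatment,
    max_log_lik = x$profile$max_ll,
    n_draws = x$profile$n_draws,
    seed = x$profile$seed %||% NA_integer_,
    ss_clamped = x$profile$ss_clamped
  )
}
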