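#' Wilson score confidence interval for a binomial proportion
#'
#' Score-test-based interval for k successes out of n trials, with or
#' without the continuity correction. Both variants invert the normal
#' approximation to the score test; the corrected form widens each bound by
#' the 1/(2n) continuity term and is never narrower than the plain form.
#' Bounds are clipped to \[0, 1\], and the corrected bounds are exactly 0
#' (resp. 1) when k = 0 (resp. k = n).
#'
#' @param k number of successes (vectorized).
#' @param n number of trials, n >= 1.
#' @param level confidence level, default 0.95.
#' @param continuity apply the continuity correction (default `TRUE`).
#' @return tibble with columns `k`, `n`, `p_hat`, `lower`, `upper`,
#'   `method`, `level`.
#' @export
#' @examples
#' wilson_ci(376, 601, continuity = FALSE)
wilson_ci <- function(k, n, level = 0.95, continuity = TRUE) {
  if (any(n < 1)) stop("undefined proportion: n must be >= 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  if (continuity) {
    lower <- (2 * n * p + z^2 - 1 -
                z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
      (2 * (n + z^2))
    upper <- (2 * n * p + z^2 + 1 +
                z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
      (2 * (n + z^2))
    lower[k == 0] <- 0
    upper[k == n] <- 1
  } else {
    centre <- p + z^2 / (2 * n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    lower <- (centre - half) / (1 + z^2 / n)
    upper <- (centre + half) / (1 + z^2 / n)
  }
  tibble::tibble(
    k = k, n = n, p_hat = p,
    lower = pmin(pmax(lower, 0), p),
    upper = pmax(pmin(upper, 1), p),
    method = if (continuity) "WILSON_CC" else "WILSON",
    level = level
  )
}

# central moments (1..4) and normalizing mass of a Poisson(lambda)
# truncated to [lambda - c, lambda + c]; returns c(mom1..mom4, mass)
sg_moments <- function(c, lambda) {
  a <- lambda + c
  b <- max(lambda - c, 0)
  den <- ppois(a, lambda) - ppois(b - 1, lambda)
  mu <- numeric(4)
  for (r in 1:4) {
    pois_a <- if (a - r >= 0) ppois(a, lambda) - ppois(a - r, lambda) else 0
    pois_b <- if (b - r - 1 >= 0) {
      ppois(b - 1, lambda) - ppois(b - r - 1, lambda)
    } else 0
    mu[r] <- lambda^r * (1 - (pois_a - pois_b) / den)
  }
  mom <- numeric(5)
  mom[1] <- mu[1]
  mom[2] <- mu[2] + mu[1] - mu[1]^2
  mom[3] <- mu[3] + mu[2] * (3 - 3 * mu[1]) +
    (mu[1] - 3 * mu[1]^2 + 2 * mu[1]^3)
  mom[4] <- mu[4] + mu[3] * (6 - 4 * mu[1]) +
    mu[2] * (7 - 12 * mu[1] + 6 * mu[1]^2) +
    mu[1] - 4 * mu[1]^2 + 6 * mu[1]^3 - 3 * mu[1]^4
  mom[5] <- den
  mom
}

# Edgeworth-corrected probability that independent truncated Poissons
# (truncation half-width c, means = the observed counts) sum to n, relative
# to the untruncated conditional; the simultaneous coverage of the +/- c box.
sg_coverage <- function(c, counts) {
  n <- sum(counts)
  m <- t(vapply(counts, function(x) sg_moments(c, x), numeric(5)))
  m[, 4] <- m[, 4] - 3 * m[, 2]^2   # fourth cumulant
  s1 <- sum(m[, 1]); s2 <- sum(m[, 2])
  s3 <- sum(m[, 3]); s4 <- sum(m[, 4])
  z <- (n - s1) / sqrt(s2)
  g1 <- s3 / s2^1.5
  g2 <- s4 / s2^2
  poly <- 1 + g1 * (z^3 - 3 * z) / 6 +
    g2 * (z^4 - 6 * z^2 + 3) / 24 +
    g1^2 * (z^6 - 15 * z^4 + 45 * z^2 - 15) / 72
  f <- poly * exp(-z^2 / 2) / sqrt(2 * pi)
  probn <- 1 / (ppois(n, n) - ppois(n - 1, n))
  probn * prod(m[, 5]) * f / sqrt(s2)
}

#' Sison-Glaz simultaneous confidence intervals for multinomial proportions
#'
#' Simultaneous intervals with a common half-width c/N (plus an interpolation
#' term 2*delta/N on the upper bounds), where the integer c is calibrated so
#' that the joint coverage of the +/- c box around the observed counts --
#' approximated by an Edgeworth expansion of the conditioned truncated-
#' Poisson representation of the multinomial -- reaches the nominal level.
#'
#' @param counts nonnegative integer category counts (>= 2 categories,
#'   total >= 1).
#' @param level confidence level, default 0.95.
#' @return tibble with one row per category: `category`, `k`, `n`, `p_hat`,
#'   `lower`, `upper`, `method`, `level`.
#' @export
#' @examples
#' sison_glaz_ci(c(SUCCESS = 44, FAIL_ALIVE = 1, FAIL_KD = 43))
sison_glaz_ci <- function(counts, level = 0.95) {
  if (length(counts) < 2) stop("need >= 2 categories", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("undefined proportions: total count is 0", call. = FALSE)
  p <- counts / n
  c_int <- 1
  cov_prev <- sg_coverage(0, counts)
  cov_cur <- sg_coverage(c_int, counts)
  while (cov_cur < level && c_int < n) {
    c_int <- c_int + 1
    cov_prev <- cov_cur
    cov_cur <- sg_coverage(c_int, counts)
  }
  # tau = c - 1 satisfies coverage(tau) < level <= coverage(tau + 1);
  # delta interpolates between the two coverages
  delta <- (level - cov_prev) / (cov_cur - cov_prev)
  delta <- min(max(delta, 0), 1)
  c_eff <- c_int - 1
  tibble::tibble(
    category = if (!is.null(names(counts))) names(counts) else
      as.character(seq_along(counts)),
    k = as.numeric(counts),
    n = n,
    p_hat = p,
    lower = pmax(p - c_eff / n, 0),
    upper = pmin(p + c_eff / n + 2 * delta / n, 1),
    method = "SISON_GLAZ",
    level = level
  )
}

#' Share of knock-down among failed mosquitoes
#'
#' Of the mosquitoes that failed to pass through the net, the fraction that
#' were knocked down rather than alive. Undefined when a cell has no
#' failures.
#'
#' @param n_fail_alive,n_fail_kd failure counts (vectorized).
#' @return numeric vector `n_fail_kd / (n_fail_alive + n_fail_kd)`.
#' @export
#' @examples
#' kd_share_of_failures(1, 43)  # 43/44 = 0.977...
kd_share_of_failures <- function(n_fail_alive, n_fail_kd) {
  n_fail <- n_fail_alive + n_fail_kd
  if (any(n_fail < 1)) {
    stop("undefined knock-down share: cell has no failures", call. = FALSE)
  }
  n_fail_kd / n_fail
}

#' Tidy proportion summaries of an outcome table
#'
#' Per genotype x treatment cell: the success proportion with its Wilson
#' interval, and (for cells with failures on treated nets) the knock-down
#' share among failures with a Wilson interval on the failure subset.
#'
#' @param table outcome table (see [as_outcome_table()]).
#' @param level confidence level.
#' @param continuity continuity correction for the Wilson intervals.
#' @return tibble with columns `genotype`, `treatment`, `measure`
#'   (`"success"` or `"kd_share"`), `k`, `n`, `p_hat`, `lower`, `upper`,
#'   `method`, `level`.
#' @export
outcome_proportions <- function(table, level = 0.95, continuity = TRUE) {
  table <- as_outcome_table(table)
  keep <- table$n_total > 0
  succ <- dplyr::bind_cols(
    table[keep, c("genotype", "treatment")],
    measure = "success",
    wilson_ci(table$n_success[keep], table$n_total[keep], level, continuity)
  )
  fail <- table$n_fail_alive + table$n_fail_kd
  kd_keep <- fail > 0 & table$treatment != "UTN"
  kd <- dplyr::bind_cols(
    table[kd_keep, c("genotype", "treatment")],
    measure = "kd_share",
    wilson_ci(table$n_fail_kd[kd_keep], fail[kd_keep], level, continuity)
  )
  dplyr::bind_rows(succ, kd)
}
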