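# Independent oracles and fixture generators used across the suite.

# invert the binomial score test by bisection (with or without the
# continuity term); independent of the closed-form Wilson expressions
score_ci_oracle <- function(k, n, level = 0.95, continuity = FALSE) {
  z <- qnorm(1 - (1 - level) / 2)
  stat <- function(p0) {
    num <- abs(k / n - p0) - if (continuity) 1 / (2 * n) else 0
    max(num, 0) / sqrt(p0 * (1 - p0) / n)
  }
  bisect <- function(lo, hi, inside_at_lo) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if ((stat(mid) <= z) == inside_at_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  p <- k / n
  lower <- if (stat(1e-12) <= z) 0 else bisect(1e-12, p, FALSE)
  upper <- if (stat(1 - 1e-12) <= z) 1 else bisect(p, 1 - 1e-12, TRUE)
  c(lower = lower, upper = upper)
}

# random binomial outcome table (3 genotypes x chosen treatments) with
# non-degenerate success counts
random_success_table <- function(treatments = c("UTN", "OLYSET"),
                                 n_range = c(20, 100)) {
  grid <- expand.grid(genotype = c("SS", "RS", "RR"),
                      treatment = treatments,
                      stringsAsFactors = FALSE)
  n <- sample(seq(n_range[1], n_range[2]), nrow(grid), replace = TRUE)
  p <- runif(nrow(grid), 0.15, 0.85)
  k <- pmin(pmax(rbinom(nrow(grid), n, p), 1), n - 1)
  kdrfitness::as_outcome_table(tibble::tibble(
    genotype = grid$genotype, treatment = grid$treatment,
    n_success = k, n_fail_alive = n - k, n_fail_kd = 0L
  ))
}

# random three-outcome table on the treated nets, every category >= 1
random_kd_table <- function() {
  grid <- expand.grid(genotype = c("SS", "RS", "RR"),
                      treatment = c("OLYSET", "PERMANET"),
                      stringsAsFactors = FALSE)
  counts <- t(vapply(seq_len(nrow(grid)), function(i) {
    n <- sample(30:120, 1)
    repeat {
      y <- as.integer(stats::rmultinom(1, n, runif(3, 0.2, 1)))
      if (all(y >= 1)) return(y)
    }
  }, integer(3)))
  kdrfitness::as_outcome_table(tibble::tibble(
    genotype = grid$genotype, treatment = grid$treatment,
    n_success = counts[, 1], n_fail_alive = counts[, 2],
    n_fail_kd = counts[, 3]
  ))
}

# 2-D grid-search profile-likelihood oracle over (a_RS, a_RR): evaluates the
# joint binomial log-likelihood (a_SS profiled analytically) on a res x res
# grid and reads likelihood-ratio CI endpoints for s or h directly off the
# grid points, with no Monte-Carlo sampling and no binning
grid_profile_oracle <- function(table, treatment, parameter,
                                level = 0.95, res = 2001, box = NULL,
                                s_range = c(-1, 1), h_range = c(-5, 105)) {
  cells <- table[table$treatment == treatment, ]
  k <- setNames(cells$n_success[match(c("SS", "RS", "RR"),
                                      cells$genotype)], c("SS", "RS", "RR"))
  n <- setNames(cells$n_total[match(c("SS", "RS", "RR"),
                                    cells$genotype)], c("SS", "RS", "RR"))
  grid_of <- function(g) {
    if (!is.null(box)) return(seq(box[1], box[2], length.out = res))
    p_sm <- (k[[g]] + 0.5) / (n[[g]] + 1)
    a_hat <- qlogis(p_sm)
    half <- max(6 / sqrt(n[[g]] * p_sm * (1 - p_sm)), 1.5)
    seq(max(a_hat - half, -12), min(a_hat + half, 12), length.out = res)
  }
  p_rs_grid <- plogis(grid_of("RS"))
  p_rr_grid <- plogis(grid_of("RR"))
  p_ss <- k[["SS"]] / n[["SS"]]
  ll_ss <- dbinom(k[["SS"]], n[["SS"]], p_ss, log = TRUE)
  ll_rs <- dbinom(k[["RS"]], n[["RS"]], p_rs_grid, log = TRUE)
  ll_rr <- dbinom(k[["RR"]], n[["RR"]], p_rr_grid, log = TRUE)
  ll <- outer(ll_rs, ll_rr, "+") + ll_ss       # [a_RS, a_RR]
  s_col <- p_rr_grid / p_ss - 1                 # depends on a_RR only
  thr <- max(ll) - qchisq(level, 1) / 2
  above <- ll >= thr
  if (parameter == "s") {
    vals <- matrix(rep(s_col, each = res), nrow = res)
  } else {
    w_rs <- p_rs_grid / p_ss                    # rows
    vals <- outer(w_rs - 1, s_col, "/")
  }
  rng <- if (parameter == "s") s_range else h_range
  v <- vals[above]
  list(
    lower = min(v[v >= rng[1]], Inf),
    upper = max(v[v <= rng[2]], -Inf),
    lower_unbounded = any(v < rng[1]),
    upper_unbounded = any(v > rng[2])
  )
}

# tie-corrected Kruskal-Wallis H computed from first principles
kw_h_oracle <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / as.integer(table(g))) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
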