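make_contact_trials <- function(rates = c(SS = 1.2, RS = 1.2, RR = 0.4),
                                n = 40, seed = 1) {
  set.seed(seed)
  purrr::imap_dfr(rates, function(rate, g) {
    dur <- runif(n, 600, 3600)
    tibble::tibble(
      trial_id = paste0(g, seq_len(n)),
      genotype = g, treatment = "UTN", outcome = "FAIL_ALIVE",
      duration_s = 3600,
      n_net_contacts = rpois(n, rate / 60 * 3600)
    )
  })
}

test_that("contact-rate ratios equal empirical rate ratios (saturated)", {
  set.seed(17)
  for (i in 1:20) {
    trials <- make_contact_trials(
      rates = c(SS = runif(1, 0.5, 2), RR = runif(1, 0.5, 2)),
      n = 30, seed = i
    )
    res <- contact_rate_model(trials)
    rate <- function(g) {
      d <- trials[trials$genotype == g, ]
      sum(d$n_net_contacts) / sum(d$duration_s)
    }
    expect_equal(res$crr[res$contrast == "RR-vs-SS"], rate("RR") / rate("SS"),
                 tolerance = 1e-8)
  }
})

test_that("the reference genotype's fitted rate is the empirical rate", {
  trials <- make_contact_trials(n = 25, seed = 9)
  dat <- trials[trials$genotype %in% c("SS", "RR"), ]
  dat$genotype <- factor(dat$genotype, levels = c("SS", "RR"))
  fit <- glm(n_net_contacts ~ genotype + offset(log(duration_s)),
             family = poisson(), data = dat)
  emp_rr <- sum(dat$n_net_contacts[dat$genotype == "RR"]) /
    sum(dat$duration_s[dat$genotype == "RR"])
  emp_ss <- sum(dat$n_net_contacts[dat$genotype == "SS"]) /
    sum(dat$duration_s[dat$genotype == "SS"])
  expect_equal(exp(sum(coef(fit))), emp_rr, tolerance = 1e-8)
  expect_equal(exp(coef(fit)[[1]]), emp_ss, tolerance = 1e-8)
})

test_that("rate ratios invert and ignore a common duration rescaling", {
  trials <- make_contact_trials(seed = 3)
  res <- contact_rate_model(trials)
  rr_ss <- res$crr[res$contrast == "RR-vs-SS"]
  rs_ss <- res$crr[res$contrast == "RS-vs-SS"]
  rr_rs <- res$crr[res$contrast == "RR-vs-RS"]
  expect_equal(rr_ss / rs_ss, rr_rs, tolerance = 1e-10)

  # the offset absorbs a common rescaling of durations into the intercept
  scaled <- trials
  scaled$duration_s <- trials$duration_s  # durations fixed by design;
  dat <- trials
  dat$duration_s <- dat$duration_s / 60   # minutes instead of seconds
  dat$time_to_pass_s <- NULL
  fit_s <- glm(n_net_contacts ~ genotype + offset(log(duration_s)),
               family = poisson(), data = trials)
  fit_m <- glm(n_net_contacts ~ genotype + offset(log(duration_s)),
               family = poisson(), data = dat)
  expect_equal(coef(fit_s)[-1], coef(fit_m)[-1], tolerance = 1e-8)
})

test_that("equal rates give CRR near 1; zero-count genotype is corrected", {
  trials <- make_contact_trials(rates = c(SS = 1, RS = 1, RR = 1), n = 200,
                                seed = 5)
  res <- contact_rate_model(trials)
  expect_true(all(res$conf.low < 1 & 1 < res$conf.high))

  zero <- make_contact_trials(rates = c(SS = 1, RR = 1), n = 10, seed = 6)
  zero$n_net_contacts[zero$genotype == "RR"] <- 0L
  res0 <- contact_rate_model(zero)
  expect_true(all(res0$corrected))
  expect_true(all(is.finite(res0$crr)))
})

test_that("Kruskal-Wallis H matches the direct rank-sum formula", {
  expect_equal(kruskal_wallis(1:9, rep(1:3, each = 3))$statistic,
               kw_h_oracle(1:9, rep(1:3, each = 3)), tolerance = 1e-12)
  set.seed(23)
  for (i in 1:20) {
    x <- sample(round(rnorm(45, 0, 3)))   # rounded values force ties
    g <- rep(1:3, each = 15)
    expect_equal(kruskal_wallis(x, g)$statistic, kw_h_oracle(x, g),
                 tolerance = 1e-10)
  }
  # identical data across groups
  same <- kruskal_wallis(rep(2, 9), rep(1:3, each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("H is invariant to strictly monotone transformations", {
  set.seed(29)
  x <- rexp(60)
  g <- rep(1:3, each = 20)
  h0 <- kruskal_wallis(x, g)$statistic
  expect_equal(kruskal_wallis(log(x), g)$statistic, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(x^3, g)$statistic, h0, tolerance = 1e-12)
})

test_that("the chi-square reference matches a permutation null", {
  set.seed(31)
  x <- c(rnorm(15, 0), rnorm(15, 0.9), rnorm(15, 0.4))
  g <- rep(1:3, each = 15)
  h_obs <- kw_h_oracle(x, g)
  perm <- replicate(20000, kw_h_oracle(x, sample(g)))
  p_perm <- mean(perm >= h_obs - 1e-12)
  p_chisq <- kruskal_wallis(x, g)$p.value
  expect_lt(abs(p_perm - p_chisq), 0.02)
})

test_that("Dunn z statistics reduce to H for two groups and to the
           mean-rank formula in general", {
  set.seed(37)
  x <- rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  z <- dunn_posthoc(x, g)$z
  expect_equal(z^2, kruskal_wallis(x, g)$statistic, tolerance = 1e-10)

  # direct mean-rank oracle with tie correction, three groups
  x <- sample(round(rnorm(60, 0, 2)))
  g <- rep(c("a", "b", "c"), each = 20)
  res <- dunn_posthoc(x, g, adjustment = "none")
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  v <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / sqrt(v * (1 / 20 + 1 / 20))
  expect_equal(res$z[res$contrast == "a-vs-b"], z_ab, tolerance = 1e-10)

  # identical groups: all adjusted p = 1
  flat <- dunn_posthoc(rep(1:5, 3), rep(c("a", "b", "c"), each = 5))
  expect_true(all(flat$p.adjusted == 1))
  # adjusted never below raw
  expect_true(all(res$p.adjusted >= res$p.value))
})

test_that("behavior_summary analyzes available traits and skips others", {
  trials <- simulate_trials(sim_config(), seed = 8)
  out <- behavior_summary(trials)
  expect_s3_class(out$contact_rates, "tbl_df")
  expect_true(all(c("flight_time_fraction", "mean_speed",
                    "time_to_pass_s") %in% out$rank_tests$variable))
  bare <- trials[c("trial_id", "genotype", "treatment", "outcome",
                   "duration_s", "n_net_contacts")]
  out2 <- behavior_summary(bare)
  expect_equal(nrow(out2$rank_tests), 0)
})
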