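test_that("relative fitness and its decomposition follow the definitions", {
  w <- decompose_fitness(w_RS = 0.975, w_RR = 0.6375)
  expect_equal(w$s, -0.3625)
  expect_equal(w$h, (0.975 - 1) / -0.3625)

  expect_equal(decompose_fitness(0.7, 0.7)$h, 1)   # dominant cost
  expect_equal(decompose_fitness(1, 0.7)$h, 0)     # recessive cost
  expect_false(decompose_fitness(1, 1)$h_defined)  # s = 0, h undefined

  # round trip: (h, s) -> (w_RS, w_RR) -> (h, s)
  set.seed(3)
  for (i in 1:50) {
    s <- runif(1, -0.9, 0.9)
    if (abs(s) < 0.01) next
    h <- runif(1, -2, 5)
    out <- decompose_fitness(1 + h * s, 1 + s)
    expect_equal(out$s, s, tolerance = 1e-12)
    expect_equal(out$h, h, tolerance = 1e-9)
  }

  tab <- kdr_assay_counts()
  w_utn <- relative_fitness(tab, "UTN")
  expect_equal(w_utn$w_RS, (31 / 40) / (52 / 65))
  expect_equal(w_utn$w_RR, (32 / 62) / (52 / 65))

  # identical proportions give unit fitness
  flat <- tibble::tibble(
    genotype = c("SS", "RS", "RR"), treatment = "UTN",
    n_success = 20L, n_fail_alive = 20L, n_fail_kd = 0L
  )
  expect_equal(relative_fitness(flat, "UTN")$w_RR, 1)

  # lethal-equivalent boundary
  dead <- flat
  dead$n_success[3] <- 0L
  dead$n_fail_alive[3] <- 40L
  w0 <- relative_fitness(dead, "UTN")
  expect_equal(w0$w_RR, 0)
  expect_equal(decompose_fitness(w0$w_RS, w0$w_RR)$s, -1)
})

test_that("profiling a_SS analytically matches numerical maximization", {
  set.seed(21)
  for (i in 1:10) {
    tab <- random_success_table(treatments = "UTN")
    closed <- mc_profile(tab, "UTN", n_draws = 10, seed = 1)
    numeric <- mc_profile(tab, "UTN", n_draws = 10, seed = 1,
                          profile_a_ss = "numeric")
    expect_equal(closed$draws$a_SS[1], numeric$draws$a_SS[1],
                 tolerance = 1e-6)
  }
})

test_that("the envelope attains the saturated maximum at the MLE", {
  tab <- kdr_assay_counts()
  for (t in c("UTN", "OLYSET")) {
    prof <- mc_profile(tab, t, n_draws = 5000, seed = 2)
    cells <- tab[tab$treatment == t, ]
    ll_sat <- sum(dbinom(cells$n_success, cells$n_total,
                         cells$n_success / cells$n_total, log = TRUE))
    expect_equal(prof$max_ll, ll_sat, tolerance = 1e-9)
    expect_true(all(prof$envelope_s$max_ll <= prof$max_ll + 1e-12,
                    na.rm = TRUE))
    # the bin containing the analytic MLE attains the global maximum
    s_hat <- prof$mle$s
    bin <- which(prof$envelope_s$lower <= s_hat &
                   prof$envelope_s$upper > s_hat)
    expect_equal(prof$envelope_s$max_ll[bin], prof$max_ll,
                 tolerance = 1e-6)
  }
})

test_that("envelope bins never decrease when draws are added", {
  set.seed(14)
  x1 <- runif(2000, -1, 1); ll1 <- -abs(x1) * 3 + rnorm(2000, 0, 0.2)
  x2 <- runif(3000, -1, 1); ll2 <- -abs(x2) * 3 + rnorm(3000, 0, 0.2)
  small <- kdrfitness:::bin_envelope(x1, ll1, c(-1, 1), 64)$curve$max_ll
  big <- kdrfitness:::bin_envelope(c(x1, x2), c(ll1, ll2),
                                   c(-1, 1), 64)$curve$max_ll
  idx <- !is.na(small)
  expect_true(all(big[idx] >= small[idx]))
})

test_that("a quadratic envelope yields the Gaussian-limit interval", {
  sigma <- 0.07
  theta_hat <- -0.3
  mids <- seq(-1, 1, length.out = 513)[-1] - 1 / 512
  env <- tibble::tibble(
    bin = seq_along(mids),
    mid = mids,
    lower = mids - 1 / 512,
    upper = mids + 1 / 512,
    max_ll = -(mids - theta_hat)^2 / (2 * sigma^2)
  )
  prof <- structure(
    list(envelope_s = env, max_ll = 0,
         overflow_s = c(lower = -Inf, upper = -Inf),
         mle = tibble::tibble(s = theta_hat), s_range = c(-1, 1)),
    class = "kdr_profile"
  )
  ci <- lr_ci(prof, "s")
  expect_equal(ci$lower, theta_hat - 1.96 * sigma, tolerance = 2 / 512)
  expect_equal(ci$upper, theta_hat + 1.96 * sigma, tolerance = 2 / 512)
  expect_false(ci$lower_unbounded || ci$upper_unbounded)
})

test_that("selection and dominance are recovered from synthetic trials", {
  config <- sim_config(
    n = matrix(c(5000, 5000, 5000, 0, 0, 0, 0, 0, 0), nrow = 3,
               dimnames = list(c("SS", "RS", "RR"),
                               c("UTN", "OLYSET", "PERMANET")))
  )
  trials <- simulate_trials(config, seed = 1)
  tab <- tabulate_outcomes(trials)
  fit <- estimate_fitness(tab, "UTN", n_draws = 30000, seed = 1)
  expect_gt(fit$estimates$s, -0.40)
  expect_lt(fit$estimates$s, -0.30)
  expect_gt(fit$estimates$h, 0)
  expect_lt(fit$estimates$h, 0.25)
  # the interval for s excludes 0, h is finitely bounded near 0
  expect_lt(fit$estimates$s_upper, 0)
  expect_false(fit$estimates$h_upper_unbounded)
})

test_that("overdominant treated-net data flag the h upper bound unbounded", {
  fit <- estimate_fitness(kdr_assay_counts(), "OLYSET", n_draws = 50000,
                          seed = 4)
  expect_gt(fit$estimates$s, 0)
  expect_gt(fit$estimates$h, 1)
  expect_true(fit$estimates$h_upper_unbounded)
})

test_that("Monte-Carlo interval endpoints agree with the grid oracle", {
  tab <- kdr_assay_counts()
  prof <- mc_profile(tab, "UTN", n_draws = 100000, seed = 6)
  for (param in c("s", "h")) {
    ci <- lr_ci(prof, param)
    oracle <- grid_profile_oracle(tab, "UTN", param, res = 801)
    width <- if (param == "s") prof$bin_width_s else prof$bin_width_h
    expect_lt(abs(ci$lower - oracle$lower), 2 * width)
    expect_lt(abs(ci$upper - oracle$upper), 2 * width)
  }
})

test_that("degenerate SS cells are clamped and flagged", {
  tab <- tibble::tibble(
    genotype = c("SS", "RS", "RR"), treatment = "UTN",
    n_success = c(30L, 20L, 10L), n_fail_alive = c(0L, 10L, 20L),
    n_fail_kd = 0L
  )
  prof <- mc_profile(tab, "UTN", n_draws = 1000, seed = 1)
  expect_true(prof$ss_clamped)
})
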