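test_that("the saturated multinomial fit reproduces empirical fractions", {
  set.seed(5)
  for (i in 1:20) {
    tab <- random_kd_table()
    fit <- fit_kd_model(tab)
    probs <- as.matrix(fit$fitted[c("SUCCESS", "FAIL_ALIVE", "FAIL_KD")])
    emp <- as.matrix(fit$fitted[paste0("emp_", c("SUCCESS", "FAIL_ALIVE",
                                                 "FAIL_KD"))])
    expect_lt(max(abs(rowSums(probs) - 1)), 1e-10)
    expect_lt(max(abs(probs - emp)), 1e-6)
    # log-likelihood equals the sum of multinomial log-pmfs at the MLE
    y <- fit$counts
    ll_direct <- sum(vapply(seq_len(nrow(y)), function(j) {
      dmultinom(y[j, ], prob = y[j, ] / sum(y[j, ]), log = TRUE)
    }, numeric(1)))
    expect_equal(fit$log_lik, ll_direct, tolerance = 1e-6)
  }
})

test_that("identical cell compositions give null effects", {
  tab <- tidyr::expand_grid(genotype = c("SS", "RS", "RR"),
                            treatment = c("OLYSET", "PERMANET")) |>
    dplyr::mutate(n_success = 30L, n_fail_alive = 10L, n_fail_kd = 20L)
  fit <- fit_kd_model(tab)
  non_intercept <- fit$coefficients[, -1, drop = FALSE]
  expect_lt(max(abs(non_intercept)), 1e-8)
})

test_that("knock-down odds ratios equal the conditional cross-ratio", {
  set.seed(8)
  for (i in 1:200) {
    tab <- random_kd_table()
    fit <- fit_kd_model(tab)
    g <- sample(c("SS", "RS", "RR"), 1)
    res <- kd_vs_alive_or(fit, g)
    c1 <- tab[tab$genotype == g & tab$treatment == "PERMANET", ]
    c2 <- tab[tab$genotype == g & tab$treatment == "OLYSET", ]
    cross <- (c1$n_fail_kd / c1$n_fail_alive) /
      (c2$n_fail_kd / c2$n_fail_alive)
    expect_equal(res$or, cross, tolerance = 1e-6)
  }
})

test_that("symmetric failure counts give OR = 1; zeros are corrected", {
  tab <- tidyr::expand_grid(genotype = c("SS", "RS", "RR"),
                            treatment = c("OLYSET", "PERMANET")) |>
    dplyr::mutate(n_success = 20L, n_fail_alive = 10L, n_fail_kd = 10L)
  fit <- fit_kd_model(tab)
  expect_equal(kd_vs_alive_or(fit, "RS")$or, 1, tolerance = 1e-8)

  tab$n_fail_kd[tab$genotype == "SS" & tab$treatment == "OLYSET"] <- 0L
  fit0 <- fit_kd_model(tab)
  res <- kd_vs_alive_or(fit0, "SS")
  expect_true(res$corrected)
  expect_true(is.finite(res$or))
})

test_that("collapsing the failure categories reproduces the binomial fit", {
  set.seed(13)
  tab <- random_kd_table()
  multi <- fit_kd_model(tab)
  bin <- fit_success_model(tab, reference = c("SS", "OLYSET"))
  succ_multi <- multi$fitted$SUCCESS[order(multi$fitted$genotype,
                                           multi$fitted$treatment)]
  succ_bin <- bin$fitted$p_fitted[order(as.character(bin$fitted$genotype),
                                        as.character(bin$fitted$treatment))]
  expect_equal(succ_multi, succ_bin, tolerance = 1e-7)
})

test_that("the Newton fit agrees with an independent multinomial fitter", {
  skip_if_not_installed("nnet")
  tab <- kdr_assay_counts()
  fit <- fit_kd_model(tab)
  treated <- tab[tab$treatment != "UTN", ]
  long <- treated |>
    tidyr::pivot_longer(c("n_success", "n_fail_alive", "n_fail_kd"),
                        names_to = "outcome", values_to = "n")
  ref <- nnet::multinom(
    factor(outcome, levels = c("n_success", "n_fail_alive", "n_fail_kd")) ~
      genotype * treatment,
    weights = n, data = long, trace = FALSE, maxit = 1000, reltol = 1e-14
  )
  ref_probs <- stats::predict(ref, newdata = treated, type = "probs")
  own_probs <- as.matrix(fit$fitted[c("SUCCESS", "FAIL_ALIVE", "FAIL_KD")])
  expect_lt(max(abs(unname(ref_probs) - unname(own_probs))), 1e-3)
})

test_that("reported knock-down contrasts match the printed analysis", {
  res <- kd_treatment_contrasts(kdr_assay_counts())
  expect_equal(res$or[res$genotype == "SS"], 0.861, tolerance = 0.01)
  expect_equal(res$or[res$genotype == "RR"], 1.483, tolerance = 0.01)
  # the printed RS value (12.911) reflects the original optimizer; the
  # saturated cross-ratio is (11/1)/(6/7)
  expect_equal(res$or[res$genotype == "RS"], (11 / 1) / (6 / 7),
               tolerance = 1e-6)
  expect_lt(res$p.value[res$genotype == "RS"], 0.05)
})

test_that("an unobserved category is dropped with a warning", {
  tab <- tidyr::expand_grid(genotype = c("SS", "RS", "RR"),
                            treatment = c("OLYSET", "PERMANET")) |>
    dplyr::mutate(n_success = 20L, n_fail_alive = 10L, n_fail_kd = 0L)
  expect_warning(fit <- fit_kd_model(tab), "unobserved")
  expect_equal(fit$categories, "FAIL_ALIVE")
})
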