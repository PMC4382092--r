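#' Binomial logistic model of hole-penetration success
#'
#' Fits the saturated binomial logistic model
#' `logit P(success) = b0 + genotype + treatment + genotype:treatment`
#' to a genotype x treatment outcome table, pooling the two failure
#' categories (alive and knocked down). With the full factorial the model is
#' saturated, so fitted cell probabilities equal the empirical proportions
#' and the deviance is zero; inference on contrasts is Wald, using the
#' coefficient covariance.
#'
#' @param table outcome table (see [as_outcome_table()]). Cells with zero
#'   totals are dropped.
#' @param reference length-2 character vector `c(genotype, treatment)` used
#'   as the reference cell for dummy coding.
#' @return an object of class `kdr_success_fit` with elements `fit` (the
#'   underlying `glm`), `coefficients`, `vcov`, `log_lik`, `fitted` (tibble
#'   of per-cell fitted and empirical success probabilities), `reference`
#'   and `table`.
#' @export
fit_success_model <- function(table, reference = c("SS", "UTN")) {
  table <- as_outcome_table(table)
  table <- table[table$n_total > 0, ]
  stopifnot(reference[1] %in% GENOTYPES, reference[2] %in% TREATMENTS)
  dat <- table |>
    dplyr::mutate(
      genotype = stats::relevel(
        factor(.data$genotype,
               levels = intersect(GENOTYPES, unique(.data$genotype))),
        ref = reference[1]),
      treatment = stats::relevel(
        factor(.data$treatment,
               levels = intersect(TREATMENTS, unique(.data$treatment))),
        ref = reference[2]),
      n_fail = .data$n_fail_alive + .data$n_fail_kd
    )
  has_both <- nlevels(dat$genotype) > 1 && nlevels(dat$treatment) > 1
  form <- if (has_both) {
    cbind(n_success, n_fail) ~ genotype * treatment
  } else if (nlevels(dat$genotype) > 1) {
    cbind(n_success, n_fail) ~ genotype
  } else {
    cbind(n_success, n_fail) ~ treatment
  }
  fit <- suppressWarnings(glm(
    form, family = binomial(), data = dat,
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  fitted_cells <- dat |>
    dplyr::transmute(
      .data$genotype, .data$treatment,
      p_empirical = .data$n_success / .data$n_total,
      p_fitted = as.numeric(stats::fitted(fit))
    )
  structure(
    list(
      fit = fit,
      coefficients = coef(fit),
      vcov = vcov(fit),
      log_lik = as.numeric(logLik(fit)),
      fitted = fitted_cells,
      reference = reference,
      table = table
    ),
    class = "kdr_success_fit"
  )
}

#' @export
print.kdr_success_fit <- function(x, ...) {
  cat("Binomial logistic model of hole-penetration success\n")
  cat("reference cell:", x$reference[1], "/", x$reference[2], "\n")
  cat("log-likelihood:", format(x$log_lik, digits = 6), "\n")
  print(x$fitted)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kdr_success_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * pnorm(-abs(unname(x$coefficients / se)))
  )
}

#' @exportS3Method generics::glance
glance.kdr_success_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_lik,
    deviance = x$fit$deviance,
    df.residual = x$fit$df.residual,
    nobs = sum(x$table$n_total)
  )
}

# closed-form 2x2 log odds ratio and Wald SE from a saturated model;
# Haldane-Anscombe +0.5 on all four cells when any margin is zero
or_2x2 <- function(k1, n1, k2, n2, level) {
  a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    or = exp(log_or),
    conf.low = exp(log_or - z * se),
    conf.high = exp(log_or + z * se),
    p.value = 2 * pnorm(-abs(log_or / se)),
    corrected = corrected
  )
}

#' All pairwise success odds ratios
#'
#' Every genotype pair within each treatment and every treatment pair within
#' each genotype, mirroring the successive re-leveling of the reference
#' class in the saturated model. Because the model is saturated, each
#' contrast equals the closed-form 2x2 cross-product ratio with Wald
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)`; contrasts touching a zero
#' margin get the Haldane-Anscombe +0.5 correction on all four cells and are
#' flagged in the `corrected` column.
#'
#' @param table outcome table.
#' @param level confidence level for the Wald intervals.
#' @return tibble with columns `stratum_type`, `stratum`, `contrast`
#'   (e.g. `"SS-vs-RR"`, first level in the numerator), `or`, `conf.low`,
#'   `conf.high`, `p.value`, `corrected`.
#' @export
pairwise_odds_ratios <- function(table, level = 0.95) {
  table <- as_outcome_table(table)
  table <- table[table$n_total > 0, ]
  cell <- function(g, t) table[table$genotype == g & table$treatment == t, ]
  rows <- list()
  for (t in intersect(TREATMENTS, unique(table$treatment))) {
    gs <- intersect(GENOTYPES, table$genotype[table$treatment == t])
    if (length(gs) < 2) next
    for (pair in utils::combn(gs, 2, simplify = FALSE)) {
      c1 <- cell(pair[1], t); c2 <- cell(pair[2], t)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(
          stratum_type = "treatment", stratum = t,
          contrast = paste0(pair[1], "-vs-", pair[2])
        ),
        or_2x2(c1$n_success, c1$n_total, c2$n_success, c2$n_total, level)
      )
    }
  }
  for (g in intersect(GENOTYPES, unique(table$genotype))) {
    ts <- intersect(TREATMENTS, table$treatment[table$genotype == g])
    if (length(ts) < 2) next
    for (pair in utils::combn(ts, 2, simplify = FALSE)) {
      c1 <- cell(g, pair[1]); c2 <- cell(g, pair[2])
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(
          stratum_type = "genotype", stratum = g,
          contrast = paste0(pair[1], "-vs-", pair[2])
        ),
        or_2x2(c1$n_success, c1$n_total, c2$n_success, c2$n_total, level)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# odds ratio for one contrast via the fitted model's coefficient covariance;
# used to verify that the contrast-vector route matches the closed form
or_from_fit <- function(fit, genotype1, genotype2, treatment, level = 0.95) {
  stopifnot(inherits(fit, "kdr_success_fit"))
  beta <- fit$coefficients
  dat <- fit$fit$data
  tt <- stats::delete.response(stats::terms(fit$fit))
  xvec <- function(g, t) {
    nd <- data.frame(
      genotype = factor(g, levels = levels(dat$genotype)),
      treatment = factor(t, levels = levels(dat$treatment))
    )
    stats::model.matrix(tt, data = nd)[1, names(beta)]
  }
  cv <- xvec(genotype1, treatment) - xvec(genotype2, treatment)
  log_or <- sum(cv * beta)
  se <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    or = exp(log_or),
    conf.low = exp(log_or - z * se),
    conf.high = exp(log_or + z * se),
    p.value = 2 * pnorm(-abs(log_or / se))
  )
}
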