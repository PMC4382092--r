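#' Multinomial logistic model of trial outcome on treated nets
#'
#' Fits a three-outcome multinomial logistic model (successful /
#' unsuccessful-alive / unsuccessful-knocked-down) with genotype, treatment
#' and their interaction, by exact Newton maximization of the multinomial
#' log-likelihood. The baseline category is `SUCCESS`, so the model carries
#' the success proportions along when comparing knock-down among failures.
#' Untreated-net rows are excluded (knock-down is undefined there). With the
#' full factorial the model is saturated: fitted per-cell category fractions
#' equal the empirical fractions.
#'
#' @param table outcome table; only `OLYSET` and `PERMANET` rows are used.
#' @param reference length-2 character `c(genotype, treatment)` reference
#'   cell for dummy coding.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param max_iter maximum Newton iterations.
#' @return object of class `kdr_kd_fit`: `coefficients` (matrix, one row per
#'   non-baseline category), `vcov` (covariance of the stacked coefficient
#'   vector, rows/cols named `<category>:<term>`), `log_lik`, `fitted`
#'   (per-cell fitted and empirical category fractions), `categories`,
#'   `reference`, `table`.
#' @export
fit_kd_model <- function(table, reference = c("SS", "OLYSET"),
                         tol = 1e-10, max_iter = 100) {
  table <- as_outcome_table(table)
  table <- table[table$treatment != "UTN" & table$n_total > 0, ]
  if (nrow(table) == 0) stop("no treated-net cells to fit", call. = FALSE)
  stopifnot(reference[1] %in% GENOTYPES,
            reference[2] %in% c("OLYSET", "PERMANET"))

  y <- as.matrix(table[c("n_success", "n_fail_alive", "n_fail_kd")])
  colnames(y) <- OUTCOMES
  categories <- c("FAIL_ALIVE", "FAIL_KD")
  empty <- categories[colSums(y[, categories, drop = FALSE]) == 0]
  if (length(empty) > 0) {
    warning("outcome category unobserved in all cells, dropped from model: ",
            paste(empty, collapse = ", "), call. = FALSE)
    categories <- setdiff(categories, empty)
    if (length(categories) == 0) {
      stop("no non-baseline outcome observed", call. = FALSE)
    }
  }

  dat <- data.frame(
    genotype = stats::relevel(
      factor(table$genotype,
             levels = intersect(GENOTYPES, unique(table$genotype))),
      ref = reference[1]),
    treatment = factor(table$treatment,
                       levels = intersect(c("OLYSET", "PERMANET"),
                                          unique(table$treatment)))
  )
  if (nlevels(dat$treatment) > 1) {
    dat$treatment <- stats::relevel(dat$treatment, ref = reference[2])
  }
  has_both <- nlevels(dat$genotype) > 1 && nlevels(dat$treatment) > 1
  form <- if (has_both) ~ genotype * treatment
  else if (nlevels(dat$genotype) > 1) ~ genotype else ~ treatment
  X <- stats::model.matrix(form, dat)
  p <- ncol(X)
  nc <- length(categories)
  n_tot <- rowSums(y)
  ync <- y[, categories, drop = FALSE]

  cell_ll <- function(P) {
    p_base <- pmax(1 - rowSums(P), 1e-300)
    sum((y[, "SUCCESS"]) * log(p_base)) +
      sum(ync * log(pmax(P, 1e-300)))
  }
  theta <- rep(0, nc * p)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    B <- matrix(theta, nrow = nc, byrow = TRUE)   # nc x p
    eta <- pmin(pmax(X %*% t(B), -30), 30)        # cells x nc
    denom <- 1 + rowSums(exp(eta))
    P <- exp(eta) / denom                         # fitted non-baseline probs
    score <- as.vector(vapply(seq_len(nc), function(c) {
      colSums(X * (ync[, c] - n_tot * P[, c]))
    }, numeric(p)))
    info <- matrix(0, nc * p, nc * p)
    for (c1 in seq_len(nc)) for (c2 in seq_len(nc)) {
      w <- if (c1 == c2) n_tot * P[, c1] * (1 - P[, c1])
      else -n_tot * P[, c1] * P[, c2]
      blk <- t(X) %*% (X * w)
      info[((c1 - 1) * p + 1):(c1 * p), ((c2 - 1) * p + 1):(c2 * p)] <- blk
    }
    # boundary cells (zero counts) flatten the information matrix; a small
    # ridge keeps the step defined while the affected logits drift out
    step <- tryCatch(solve(info, score), error = function(e) {
      solve(info + diag(1e-8 * max(diag(info)), nrow(info)), score)
    })
    step <- step * min(1, 5 / max(abs(step)))
    theta <- theta + step
    ll_cur <- cell_ll(P)
    if (max(abs(step)) < tol ||
        (iter > 5 && abs(ll_cur - ll_prev) < 1e-12)) break
    ll_prev <- ll_cur
  }
  B <- matrix(theta, nrow = nc, byrow = TRUE,
              dimnames = list(categories, colnames(X)))
  eta <- pmin(pmax(X %*% t(B), -30), 30)
  denom <- 1 + rowSums(exp(eta))
  P_full <- cbind(SUCCESS = 1 / denom, exp(eta) / denom)
  colnames(P_full) <- c("SUCCESS", categories)
  ll <- sum(vapply(seq_len(nrow(y)), function(j) {
    probs <- c(P_full[j, "SUCCESS"],
               if ("FAIL_ALIVE" %in% categories) P_full[j, "FAIL_ALIVE"]
               else 0,
               if ("FAIL_KD" %in% categories) P_full[j, "FAIL_KD"] else 0)
    dmultinom(y[j, ], prob = pmax(probs, 1e-300), log = TRUE)
  }, numeric(1)))
  vc <- tryCatch(solve(info), error = function(e) {
    solve(info + diag(1e-8 * max(diag(info)), nrow(info)))
  })
  nm <- as.vector(t(outer(categories, colnames(X), paste, sep = ":")))
  dimnames(vc) <- list(nm, nm)

  fitted_cells <- dplyr::bind_cols(
    table[c("genotype", "treatment")],
    tibble::as_tibble(P_full),
    tibble::as_tibble(y / n_tot) |>
      stats::setNames(paste0("emp_", OUTCOMES))
  )
  structure(
    list(
      coefficients = B, vcov = vc, log_lik = ll, fitted = fitted_cells,
      categories = categories, reference = reference, table = table,
      design = X, counts = y, iterations = iter
    ),
    class = "kdr_kd_fit"
  )
}

#' @export
print.kdr_kd_fit <- function(x, ...) {
  cat("Multinomial outcome model (baseline SUCCESS), treated nets\n")
  cat("log-likelihood:", format(x$log_lik, digits = 6), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kdr_kd_fit <- function(x, ...) {
  est <- as.vector(t(x$coefficients))
  nm <- as.vector(t(outer(rownames(x$coefficients),
                          colnames(x$coefficients), paste, sep = ":")))
  se <- sqrt(diag(x$vcov))[nm]
  tibble::tibble(
    category = rep(rownames(x$coefficients),
                   each = ncol(x$coefficients)),
    term = rep(colnames(x$coefficients), nrow(x$coefficients)),
    estimate = est,
    std.error = unname(se),
    statistic = est / unname(se),
    p.value = 2 * pnorm(-abs(est / unname(se)))
  )
}

#' @exportS3Method generics::glance
glance.kdr_kd_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_lik,
    nobs = sum(x$counts),
    iterations = x$iterations
  )
}

#' Knock-down vs alive odds ratio between two treatments
#'
#' For one genotype, the odds of being knocked down rather than alive among
#' failures, compared between two treated nets: the exponential of the
#' difference of (log-odds KD vs baseline) minus (log-odds alive vs
#' baseline) between the treatments. For the saturated fit this equals the
#' conditional cross-product ratio of the four failure counts. Wald CI and
#' p-value from the coefficient covariance; if any of the four relevant
#' counts is zero, the +0.5-corrected closed form is used instead and
#' flagged.
#'
#' @param fit a `kdr_kd_fit`.
#' @param genotype genotype to compare within.
#' @param treatments length-2: numerator treatment first (the odds ratio is
#'   treatment 1 relative to treatment 2).
#' @param level confidence level.
#' @return one-row tibble: `genotype`, `contrast`, `or`, `conf.low`,
#'   `conf.high`, `p.value`, `corrected`.
#' @export
kd_vs_alive_or <- function(fit, genotype,
                           treatments = c("PERMANET", "OLYSET"),
                           level = 0.95) {
  stopifnot(inherits(fit, "kdr_kd_fit"))
  if (!all(c("FAIL_ALIVE", "FAIL_KD") %in% fit$categories)) {
    stop("both failure categories must be present in the fit", call. = FALSE)
  }
  tab <- fit$table
  cells <- lapply(treatments, function(t) {
    tab[tab$genotype == genotype & tab$treatment == t, ]
  })
  if (any(vapply(cells, nrow, integer(1)) == 0)) {
    stop("genotype/treatment cell absent from fit", call. = FALSE)
  }
  counts4 <- c(cells[[1]]$n_fail_kd, cells[[1]]$n_fail_alive,
               cells[[2]]$n_fail_kd, cells[[2]]$n_fail_alive)
  z <- qnorm(1 - (1 - level) / 2)
  corrected <- any(counts4 == 0)
  if (corrected) {
    a <- counts4 + 0.5
    log_or <- log(a[1] * a[4] / (a[2] * a[3]))
    se <- sqrt(sum(1 / a))
  } else {
    # design rows of the two cells under the fit's factor coding
    xrows <- fit$design[match(
      paste(genotype, treatments),
      paste(tab$genotype, tab$treatment)), , drop = FALSE]
    dx <- xrows[1, ] - xrows[2, ]
    cv <- c(-dx, dx)  # (FAIL_ALIVE block, FAIL_KD block)
    names(cv) <- c(paste0("FAIL_ALIVE:", colnames(fit$design)),
                   paste0("FAIL_KD:", colnames(fit$design)))
    cv <- cv[rownames(fit$vcov)]
    est <- c(t(fit$coefficients))
    names(est) <- rownames(fit$vcov)
    log_or <- sum(cv * est)
    se <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
  }
  tibble::tibble(
    genotype = genotype,
    contrast = paste0(treatments[1], "-vs-", treatments[2]),
    or = exp(log_or),
    conf.low = exp(log_or - z * se),
    conf.high = exp(log_or + z * se),
    p.value = 2 * pnorm(-abs(log_or / se)),
    corrected = corrected
  )
}

#' Knock-down contrasts between nets for every genotype
#'
#' Convenience wrapper running [kd_vs_alive_or()] for each genotype present
#' on both treated nets.
#'
#' @inheritParams kd_vs_alive_or
#' @param table outcome table (treated-net rows used).
#' @return tibble, one row per genotype.
#' @export
kd_treatment_contrasts <- function(table,
                                   treatments = c("PERMANET", "OLYSET"),
                                   level = 0.95) {
  fit <- fit_kd_model(table)
  gs <- intersect(GENOTYPES, unique(fit$table$genotype))
  purrr::map_dfr(gs, function(g) {
    kd_vs_alive_or(fit, g, treatments = treatments, level = level)
  })
}
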