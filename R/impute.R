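# subject-visit scalar outcome value used to drive the imputation model
outcome_value <- function(rows, def) {
  if (def$kind == "ratio") {
    rowSums(rows[, def$fields, drop = FALSE]) / rows$energy_kcal * 1000
  } else if (def$kind == "mean") {
    rows$hba1c_pct
  } else {
    score_hei2005(rows, attr(def, "standards"))$hei2005_total
  }
}

# one Bayesian linear-model draw; returns predictions for Xo and Xm
pmm_predict <- function(Xo, y, Xm) {
  qrX <- qr(Xo)
  if (qrX$rank < ncol(Xo)) {         # drop collinear columns
    keep <- qrX$pivot[seq_len(qrX$rank)]
    Xo <- Xo[, keep, drop = FALSE]
    Xm <- Xm[, keep, drop = FALSE]
    qrX <- qr(Xo)
  }
  p <- ncol(Xo)
  beta_hat <- qr.coef(qrX, y)
  res <- y - Xo %*% beta_hat
  df <- max(1, nrow(Xo) - p)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- beta_hat + t(chol(XtXinv)) %*% stats::rnorm(p) * sqrt(sigma2)
  list(obs = drop(Xo %*% beta), mis = drop(Xm %*% beta))
}

#' Multiple imputation of missing outcome visits
#'
#' Produces `m` completed analysis tables for one outcome by sequential
#' regression with predictive-mean matching. Visits are processed in
#' chronological order; each missing subject-visit outcome is predicted
#' from treatment arm and the subject's (observed or already-imputed)
#' outcome at the previous and baseline visits, with a Bayesian draw of the
#' regression coefficients per imputation, and is then filled by copying
#' the full record of one of the five observed subjects whose predicted
#' values are closest (so imputed food and energy totals stay internally
#' consistent). Observed values are never altered; with no missing data the
#' `m` tables are identical copies of the input.
#'
#' @param trial A `diet_trial` or analysis table with missing subject-visit
#'   rows simply absent.
#' @param outcome One of [outcome_names()].
#' @param m Number of imputations (default 10).
#' @param seed Integer seed; the `m` completed tables are reproducible.
#' @param donors Number of nearest predictive-mean donors to draw from.
#' @param standards Standards table for HEI2005.
#' @return List of `m` complete analysis tables (every subject at every
#'   scheduled visit), with the outcome name as attribute `outcome`.
#' @export
impute_missing <- function(trial, outcome, m = 10, seed = 1L, donors = 5,
                           standards = hei_standards()) {
  if (m < 1) stop("m must be at least 1")
  def <- outcome_def(outcome)
  attr(def, "standards") <- standards
  tab <- analysis_table(trial, def)
  ids <- if (inherits(trial, "diet_trial")) trial$subjects$subject_id else unique(tab$subject_id)
  visits <- if (inherits(trial, "diet_trial")) {
    if (def$kind == "mean") trial$config$hba1c_visits else trial$config$diet_visits
  } else sort(unique(tab$visit_month))
  arm_of <- if (inherits(trial, "diet_trial")) {
    trial$subjects$arm[match(ids, trial$subjects$subject_id)]
  } else tab$arm[match(ids, tab$subject_id)]
  n <- length(ids)
  V <- length(visits)

  tab$.y <- outcome_value(tab, def)
  Y <- matrix(NA_real_, n, V, dimnames = list(ids, visits))
  ridx <- matrix(NA_integer_, n, V)    # row of tab holding each observed cell
  ii <- match(tab$subject_id, ids)
  jj <- match(tab$visit_month, visits)
  Y[cbind(ii, jj)] <- tab$.y
  ridx[cbind(ii, jj)] <- seq_len(nrow(tab))
  if (!anyNA(Y)) {
    out <- tab[order(jj, ii), setdiff(names(tab), ".y"), drop = FALSE]
    rownames(out) <- NULL
    return(structure(rep(list(out), m), outcome = outcome))
  }
  if (any(rowSums(!is.na(Y)) == 0)) {
    warning("subject(s) with no observed outcome at any visit; ",
            "imputed from the arm-level model")
  }

  set.seed(seed)
  arm01 <- as.numeric(arm_of == "treatment")
  completed <- vector("list", m)
  for (k in seq_len(m)) {
    Ycur <- Y
    new_rows <- list()
    for (v in seq_len(V)) {
      mis <- which(is.na(Ycur[, v]))
      if (!length(mis)) next
      obs <- which(!is.na(Y[, v]))
      X <- cbind(1, arm01)
      if (v > 1) X <- cbind(X, prev = Ycur[, v - 1])
      if (v > 2) X <- cbind(X, base = Ycur[, 1])
      usable <- obs[stats::complete.cases(X[obs, , drop = FALSE])]
      if (length(usable) < ncol(X) + 2) X <- cbind(1, arm01)
      pred <- pmm_predict(X[usable, , drop = FALSE], Y[usable, v],
                          X[mis, , drop = FALSE])
      for (i in seq_along(mis)) {
        d <- abs(pred$obs - pred$mis[i])
        pool <- usable[order(d)[seq_len(min(donors, length(usable)))]]
        donor <- pool[sample.int(length(pool), 1)]
        Ycur[mis[i], v] <- Y[donor, v]
        row <- tab[ridx[donor, v], , drop = FALSE]
        row$subject_id <- ids[mis[i]]
        row$arm <- arm_of[mis[i]]
        row$visit_month <- visits[v]
        new_rows[[length(new_rows) + 1L]] <- row
      }
    }
    full <- rbind(tab, do.call(rbind, new_rows))
    full <- full[order(match(full$visit_month, visits), match(full$subject_id, ids)),
                 setdiff(names(full), ".y"), drop = FALSE]
    rownames(full) <- NULL
    completed[[k]] <- full
  }
  structure(completed, outcome = outcome)
}

#' Combine estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; the total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times
#' the between-imputation variance. The pooled p-value refers the pooled
#' estimate over its total standard error to the standard
#' multiple-imputation t reference distribution.
#'
#' @param estimates Numeric vector of `m >= 2` per-imputation estimates.
#' @param variances Numeric vector of their squared standard errors.
#' @return Object of class `dq_pooled` with fields `m`, `pooled_estimate`,
#'   `within_variance`, `between_variance`, `total_variance`, `df`,
#'   `statistic`, `pooled_p`.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("Rubin's rules need at least 2 imputations")
  if (length(variances) != m) stop("estimates and variances must have equal length")
  if (any(variances < 0)) stop("variances must be non-negative")
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  total <- ubar + (1 + 1 / m) * b
  if (b > 0 && ubar > 0) {
    r <- (1 + 1 / m) * b / ubar
    df <- (m - 1) * (1 + 1 / r)^2
  } else {
    df <- Inf
  }
  stat <- if (total > 0) qbar / sqrt(total) else 0
  p <- if (total > 0) 2 * stats::pt(-abs(stat), df) else as.numeric(qbar == 0)
  structure(list(m = m, pooled_estimate = qbar, within_variance = ubar,
                 between_variance = b, total_variance = total, df = df,
                 statistic = stat, pooled_p = p), class = "dq_pooled")
}

#' @export
print.dq_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over %d imputations\n", x$m))
  cat(sprintf("  estimate %.4f, total SE %.4f (within var %.4f, between var %.4f)\n",
              x$pooled_estimate, sqrt(x$total_variance), x$within_variance,
              x$between_variance))
  cat(sprintf("  t = %.3f on %.1f df, p = %.4f\n", x$statistic, x$df, x$pooled_p))
  invisible(x)
}

#' Combine permutation p-values across imputations
#'
#' Probit (z-transform) combination: the mean of the probit-transformed
#' p-values is mapped back through the normal CDF. The rule is idempotent
#' on constant inputs and monotone in each input. Inputs of 0 are clamped
#' to `1/(n_perm + 1)` with a warning (a Monte-Carlo permutation p of
#' exactly 0 only reflects a finite permutation count); inputs of 1 are
#' kept finite by clamping just below 1.
#'
#' @param p Numeric vector of per-imputation permutation p-values.
#' @param n_perm Permutation count used, needed to clamp p = 0 inputs.
#' @return Combined p-value in (0, 1].
#' @export
combine_permutation_p <- function(p, n_perm = NULL) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    if (is.null(n_perm)) stop("p = 0 input requires n_perm for clamping")
    warning("p-value of 0 clamped to 1/(n_perm + 1)")
    p[p == 0] <- 1 / (n_perm + 1)
  }
  if (all(p == p[1])) return(p[1])        # idempotent on constants
  hi <- if (is.null(n_perm)) 1 - 1e-12 else 1 - 1 / (2 * (n_perm + 1))
  z <- stats::qnorm(pmin(p, hi))
  min(1, stats::pnorm(mean(z)))
}

#' Intent-to-treat permutation analysis with multiple imputation
#'
#' Runs the full between-group analysis for one outcome including all
#' randomized subjects: missing outcome visits are multiply imputed
#' ([impute_missing()]), the Euclidean-distance permutation test is applied
#' to each completed dataset, and the permuted p-values are combined by the
#' probit rule. The final-visit arm difference is estimated per imputation
#' with its bootstrap variance and pooled by Rubin's rules.
#'
#' @param trial A `diet_trial`.
#' @param outcome One of [outcome_names()].
#' @param m Number of imputations (default 10).
#' @param n_perm Permutations per imputed dataset (default 5000).
#' @param n_boot Bootstrap resamples for the final-visit standard errors.
#' @param seed Integer seed covering imputation, permutation and bootstrap.
#' @param standards Standards table for HEI2005.
#' @return Object of class `dq_itt`.
#' @export
itt_permutation_test <- function(trial, outcome, m = 10, n_perm = 5000,
                                 n_boot = 1000, seed = 1L,
                                 standards = hei_standards()) {
  imps <- impute_missing(trial, outcome, m = m, seed = seed,
                         standards = standards)
  no_missing <- m > 1 && identical(imps[[1]], imps[[2]])
  run <- if (no_missing) 1L else seq_len(m)
  tests <- lapply(run, function(k) {
    permutation_test(imps[[k]], outcome, n_perm = n_perm, seed = seed + k,
                     standards = standards)
  })
  p_each <- rep(vapply(tests, `[[`, numeric(1), "p_value"), length.out = m)
  combined <- combine_permutation_p(p_each, n_perm = n_perm)

  def <- outcome_def(outcome)
  final <- max(imps[[1]]$visit_month)
  est <- var <- numeric(length(run))
  for (k in seq_along(run)) {
    rows <- imps[[run[k]]]
    rows <- rows[rows$visit_month == final, , drop = FALSE]
    gv <- function(a) group_value(rows[rows$arm == a, , drop = FALSE], def, standards)
    est[k] <- gv("treatment") - gv("control")
    se2 <- vapply(c("treatment", "control"), function(a) {
      bootstrap_se(rows[rows$arm == a, , drop = FALSE],
                   function(r) group_value(r, def, standards),
                   n_boot = n_boot, seed = seed + 100L + run[k])^2
    }, numeric(1))
    var[k] <- sum(se2)
  }
  est <- rep(est, length.out = m)
  var <- rep(var, length.out = m)
  pooled <- pool_rubin(est, var)

  structure(list(outcome = outcome, m = m, n_perm = n_perm,
                 p_per_imputation = p_each, p_value = combined,
                 final_visit = final, pooled_final_difference = pooled,
                 tests = tests, seed = seed, no_missing = no_missing),
            class = "dq_itt")
}

#' @export
print.dq_itt <- function(x, ...) {
  cat("Intent-to-treat permutation analysis --", x$outcome, "\n")
  cat(sprintf("  %d imputations, %d permutations each\n", x$m, x$n_perm))
  cat(sprintf("  combined permutation p = %.4f (per-imputation range %.4f-%.4f)\n",
              x$p_value, min(x$p_per_imputation), max(x$p_per_imputation)))
  cat(sprintf("  pooled month-%s arm difference %.3f (total SE %.3f, p = %.4f)\n",
              format(x$final_visit), x$pooled_final_difference$pooled_estimate,
              sqrt(x$pooled_final_difference$total_variance),
              x$pooled_final_difference$pooled_p))
  invisible(x)
}
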