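#' Vector of visit-specific population ratios for one arm
#'
#' The arm's group-level outcome value (population-ratio density, pooled
#' HEI2005 score, or mean HbA1c) at each scheduled visit, ordered by month.
#'
#' @param trial A `diet_trial` or a subject-visit totals table from
#'   [visit_totals()] (with an `hba1c_pct` column for the `"hba1c"`
#'   outcome).
#' @param outcome One of [outcome_names()].
#' @param arm `"treatment"` or `"control"`.
#' @param standards Standards table for HEI2005.
#' @return Named numeric vector, one entry per visit month.
#' @export
visit_vector <- function(trial, outcome, arm, standards = hei_standards()) {
  def <- outcome_def(outcome)
  tab <- analysis_table(trial, def)
  visits <- if (inherits(trial, "diet_trial")) {
    if (def$kind == "mean") trial$config$hba1c_visits else trial$config$diet_visits
  } else sort(unique(tab$visit_month))   # schedule from all arms, before filtering
  tab <- tab[tab$arm == arm, , drop = FALSE]
  vapply(stats::setNames(visits, visits), function(v) {
    rows <- tab[tab$visit_month == v, , drop = FALSE]
    if (nrow(rows) == 0) {
      stop("no subjects of arm '", arm, "' at visit month ", v,
           "; cannot form the visit vector")
    }
    group_value(rows, def, standards)
  }, numeric(1))
}

#' Euclidean distance between two outcome vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @return `sqrt(sum((u - v)^2))`.
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  sqrt(sum((u - v)^2))
}

# normalise the input of the testing/estimation layer to one analysis table
analysis_table <- function(trial, def) {
  if (inherits(trial, "diet_trial")) {
    if (def$kind == "mean") {
      tab <- trial$hba1c
      tab$arm <- trial$subjects$arm[match(tab$subject_id, trial$subjects$subject_id)]
      tab
    } else {
      visit_totals(trial)
    }
  } else {
    need <- c("subject_id", "arm", "visit_month",
              if (def$kind == "mean") "hba1c_pct" else def$fields)
    missing <- setdiff(need, names(trial))
    if (length(missing)) stop("analysis table is missing columns: ",
                              paste(missing, collapse = ", "))
    trial
  }
}

# subjects x visits matrices of the fields a statistic needs, plus the
# vectorised scorer mapping pooled group totals (B x V layout) to values
perm_machine <- function(tab, def, standards) {
  visits <- sort(unique(tab$visit_month))
  ids <- unique(tab$subject_id)
  present <- table(factor(tab$subject_id, ids))
  complete <- names(present)[present == length(visits)]
  list(
    visits = visits, ids = ids, complete = complete,
    mats = if (def$kind == "ratio") {
      num <- rowSums(tab[, def$fields, drop = FALSE])
      list(num = arm_visit_matrix(cbind(tab, .num = num), ids, visits, ".num"),
           den = arm_visit_matrix(tab, ids, visits, "energy_kcal"))
    } else if (def$kind == "mean") {
      list(num = arm_visit_matrix(cbind(tab, .v = tab$hba1c_pct), ids, visits, ".v"),
           den = arm_visit_matrix(cbind(tab, .one = 1), ids, visits, ".one"))
    } else {
      m <- lapply(diet_fields(), function(f) arm_visit_matrix(tab, ids, visits, f))
      names(m) <- diet_fields()
      m
    })
}

# visit vectors (B x V) for B weighting rows over subjects, both groups
perm_vectors <- function(mach, W, def, standards) {
  V <- length(mach$visits)
  B <- nrow(W)
  if (def$kind %in% c("ratio", "mean")) {
    scale <- if (def$kind == "ratio") 1000 else 1
    g1n <- W %*% mach$mats$num; g1d <- W %*% mach$mats$den
    g0n <- matrix(colSums(mach$mats$num), B, V, byrow = TRUE) - g1n
    g0d <- matrix(colSums(mach$mats$den), B, V, byrow = TRUE) - g1d
    list(v1 = g1n / g1d * scale, v0 = g0n / g0d * scale)
  } else {
    g1 <- lapply(mach$mats, function(m) W %*% m)
    g0 <- lapply(names(mach$mats), function(f) {
      matrix(colSums(mach$mats[[f]]), B, V, byrow = TRUE) - g1[[f]]
    })
    names(g0) <- names(mach$mats)
    s1 <- score_hei2005(as.data.frame(lapply(g1, as.vector)), standards)$hei2005_total
    s0 <- score_hei2005(as.data.frame(lapply(g0, as.vector)), standards)$hei2005_total
    list(v1 = matrix(s1, B, V), v0 = matrix(s0, B, V))
  }
}

#' Permutation test of an overall treatment effect across the study
#'
#' The test statistic is the Euclidean distance between the two arms'
#' vectors of visit-specific population ratios (pooled scores for HEI2005,
#' means for HbA1c). The null distribution is generated by permuting the
#' subjects' arm labels -- a subject carries all of its visits -- and
#' recomputing both vectors and their distance for each permutation. The
#' p-value is the proportion of permuted distances at least as large as the
#' observed one (ties count as extreme; the observed labelling is not added
#' to the permutation set). Permutation is unstratified: labels are
#' reshuffled over the combined sample.
#'
#' @param trial A `diet_trial` or analysis table (see [visit_vector()]).
#'   Every subject must be observed at every visit; incomplete datasets
#'   must either be imputed first (see [impute_missing()]) or restricted
#'   with `complete_case = TRUE`.
#' @param outcome One of [outcome_names()].
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Integer seed.
#' @param complete_case Drop subjects missing any visit instead of
#'   erroring.
#' @param standards Standards table for HEI2005.
#' @return Object of class `dq_permtest`: observed distance, permutation
#'   count, count at least as extreme, p-value, seed, the two observed
#'   visit vectors and the permuted-distance quantiles.
#' @export
permutation_test <- function(trial, outcome, n_perm = 5000, seed = 1L,
                             complete_case = FALSE,
                             standards = hei_standards()) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be at least 1")
  def <- outcome_def(outcome)
  tab <- analysis_table(trial, def)
  mach <- perm_machine(tab, def, standards)
  if (length(mach$complete) < length(mach$ids)) {
    if (!complete_case) {
      stop(length(mach$ids) - length(mach$complete), " subject(s) are missing ",
           "visits; impute first or set complete_case = TRUE")
    }
    tab <- tab[tab$subject_id %in% mach$complete, , drop = FALSE]
    mach <- perm_machine(tab, def, standards)
  }
  arm_of <- tab$arm[match(mach$ids, tab$subject_id)]
  if (length(unique(arm_of)) != 2) stop("both arms must be present")
  n <- length(mach$ids)
  n1 <- sum(arm_of == "treatment")

  w_obs <- matrix(as.numeric(arm_of == "treatment"), 1, n)
  obs <- perm_vectors(mach, w_obs, def, standards)
  observed <- euclidean_distance(obs$v1[1, ], obs$v0[1, ])

  set.seed(seed)
  P <- matrix(0, n_perm, n)
  for (b in seq_len(n_perm)) P[b, sample.int(n, n1)] <- 1
  pv <- perm_vectors(mach, P, def, standards)
  dist_perm <- sqrt(rowSums((pv$v1 - pv$v0)^2))
  tol <- 1e-12 * (1 + observed)
  n_extreme <- sum(dist_perm >= observed - tol)

  structure(list(
    outcome = outcome,
    observed_distance = observed,
    n_permutations = as.integer(n_perm),
    n_at_least_as_extreme = as.integer(n_extreme),
    p_value = n_extreme / n_perm,
    seed = seed,
    n_subjects = n,
    visit_months = mach$visits,
    vector_treatment = stats::setNames(obs$v1[1, ], mach$visits),
    vector_control = stats::setNames(obs$v0[1, ], mach$visits),
    perm_quantiles = stats::quantile(dist_perm, c(0.5, 0.9, 0.95, 0.99))),
    class = "dq_permtest")
}

#' @export
print.dq_permtest <- function(x, ...) {
  cat("Euclidean-distance permutation test --", x$outcome, "\n")
  cat(sprintf("  observed distance %.4f over visits %s (n = %d subjects)\n",
              x$observed_distance, paste(x$visit_months, collapse = ", "),
              x$n_subjects))
  cat(sprintf("  %d of %d permuted distances at least as extreme: p = %.4f\n",
              x$n_at_least_as_extreme, x$n_permutations, x$p_value))
  invisible(x)
}

#' Baseline-table comparison between arms
#'
#' Two-sample pooled-variance t-test for continuous baseline variables, or
#' Pearson chi-square without continuity correction for categorical counts.
#'
#' @param x Continuous: numeric vector of per-subject values. Categorical:
#'   a counts matrix with one column per arm (categories in rows), in which
#'   case `group` is ignored.
#' @param group Factor/character of arm labels, parallel to `x`.
#' @param kind `"continuous"` or `"categorical"`.
#' @return List with `statistic`, `df`, `p_value`, `kind`.
#' @export
baseline_comparison <- function(x, group = NULL, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    g <- factor(group)
    if (nlevels(g) != 2) stop("exactly two groups are required")
    if (min(table(g)) < 2) stop("each group needs at least 2 observations")
    if (stats::var(x[g == levels(g)[1]]) == 0 && stats::var(x[g == levels(g)[2]]) == 0) {
      warning("zero variance in both groups; p set to 1")
      return(list(statistic = 0, df = length(x) - 2, p_value = 1, kind = kind))
    }
    tt <- stats::t.test(x ~ g, var.equal = TRUE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, kind = kind)
  } else {
    if (!is.matrix(x)) stop("categorical comparison needs a counts matrix")
    ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
    p <- ct$p.value
    if (is.nan(ct$statistic)) { ct$statistic <- 0; p <- 1 }
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = p, kind = kind)
  }
}
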