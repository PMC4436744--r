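#' Population-ratio density estimate
#'
#' Group-level mean intake density formed as the ratio of the group's total
#' food intake to its total energy intake, scaled per 1000 kcal. Compared
#' with averaging each subject's own short-term ratio, the population ratio
#' reduces the bias that limited record-days induce in usual-intake
#' estimates; it equals the energy-weighted mean of the individual
#' densities.
#'
#' @param food Numeric vector of per-subject food-group totals (equivalents).
#' @param energy Numeric vector of per-subject energy totals (kcal), same
#'   length as `food`, all positive.
#' @return Density in equivalents per 1000 kcal.
#' @export
population_ratio <- function(food, energy) {
  if (length(food) == 0) stop("at least one subject is required")
  if (length(food) != length(energy)) stop("food and energy must have equal length")
  if (any(!is.finite(energy)) || any(energy <= 0)) stop("every energy total must be positive")
  sum(food) / sum(energy) * 1000
}

# registry of analysis outcomes: how each maps onto intake-totals columns
outcome_def <- function(outcome) {
  ratio <- function(fields) list(kind = "ratio", fields = fields)
  defs <- list(
    wpfd = ratio(c("whole_grains", "whole_fruit", "total_vegetables",
                   "legumes", "nuts_seeds")),
    whole_grains = ratio("whole_grains"),
    fruit = ratio("total_fruit"),
    vegetables = ratio("total_vegetables"),
    legumes_nuts_seeds = ratio(c("legumes", "nuts_seeds")),
    hei2005 = list(kind = "hei", fields = diet_fields()),
    hba1c = list(kind = "mean", fields = "hba1c_pct")
  )
  if (!outcome %in% names(defs)) {
    stop("unknown outcome '", outcome, "'; available: ",
         paste(names(defs), collapse = ", "))
  }
  c(defs[[outcome]], list(name = outcome))
}

#' Names of the analysis outcomes the package understands
#' @return Character vector of outcome names accepted by the estimation and
#'   testing functions.
#' @export
outcome_names <- function() {
  c("hei2005", "wpfd", "whole_grains", "fruit", "vegetables",
    "legumes_nuts_seeds", "hba1c")
}

#' Per-subject, per-visit intake totals of a trial
#'
#' Sums each subject's record-days within each diet-assessment visit and
#' attaches the treatment arm. This is the analysis table every estimator
#' and test operates on; subjects absent from a visit (withdrawal, skipped
#' visit) simply have no row for it.
#'
#' @param trial A `diet_trial` (see [simulate_trial()]) or a data frame of
#'   record-days with `subject_id` and `visit_month` columns.
#' @param subjects Data frame with `subject_id` and `arm`; taken from the
#'   trial when a `diet_trial` is supplied.
#' @return Data frame with `subject_id`, `arm`, `visit_month`, `n_days` and
#'   the summed [diet_fields()].
#' @export
visit_totals <- function(trial, subjects = NULL) {
  if (inherits(trial, "diet_trial")) {
    subjects <- trial$subjects
    days <- trial$diet_days
  } else {
    days <- trial
  }
  if (is.null(subjects)) stop("subjects table (subject_id, arm) is required")
  key <- paste(days$subject_id, days$visit_month, sep = "\r")
  sums <- rowsum(days[diet_fields()], key)
  info <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  out <- data.frame(subject_id = info[, 1],
                    visit_month = as.numeric(info[, 2]),
                    n_days = as.vector(rowsum(rep(1L, nrow(days)), key)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, sums)
  out$arm <- subjects$arm[match(out$subject_id, subjects$subject_id)]
  rownames(out) <- NULL
  out[order(out$visit_month, out$subject_id),
      c("subject_id", "arm", "visit_month", "n_days", diet_fields())]
}

# group-level value of one outcome from a block of subject-visit totals
group_value <- function(rows, def, standards = NULL) {
  if (def$kind == "ratio") {
    num <- rowSums(rows[, def$fields, drop = FALSE])
    population_ratio(num, rows$energy_kcal)
  } else if (def$kind == "hei") {
    pooled <- as.data.frame(as.list(colSums(rows[diet_fields()])))
    score_hei2005(pooled, standards)$hei2005_total
  } else {
    mean(rows[[def$fields]])
  }
}

#' Group-level diet-quality summary by pooled totals
#'
#' Applies the population-ratio principle to a whole diet-quality index:
#' the group's intake totals are pooled (summed over subjects), converted to
#' densities, and scored once. For WPFD and individual food groups this is
#' exactly the population ratio of the constituent totals.
#'
#' @param rows Data frame of subject-visit intake totals (one row per
#'   subject) for a single group and visit.
#' @param outcome One of [outcome_names()] other than `"hba1c"`.
#' @param standards Standards table, used for `"hei2005"`.
#' @return Scalar group-level value.
#' @export
hei_population_summary <- function(rows, outcome = "hei2005",
                                   standards = hei_standards()) {
  if (nrow(rows) == 0) stop("at least one subject is required")
  def <- outcome_def(outcome)
  if (def$kind == "mean") stop("hba1c is summarised by its mean, not a pooled score")
  group_value(rows, def, standards)
}

#' Bootstrap standard error of a group-level statistic
#'
#' Resamples subjects (rows) with replacement and reports the standard
#' deviation of the statistic across resamples. The resampling unit is the
#' subject.
#'
#' @param rows Data frame of per-subject values.
#' @param statistic Function mapping such a data frame to a scalar.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return Standard error (0, with a warning, when only one subject).
#' @export
bootstrap_se <- function(rows, statistic, n_boot = 5000, seed = 1L) {
  if (!is.numeric(n_boot) || n_boot < 2) stop("n_boot must be at least 2")
  n <- nrow(rows)
  if (n < 2) {
    warning("standard error undefined with fewer than 2 subjects; returning 0")
    return(0)
  }
  set.seed(seed)
  stats::sd(vapply(seq_len(n_boot), function(b) {
    statistic(rows[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(1)))
}

# fast joint-across-visits bootstrap for one arm: W is a n_boot x n matrix of
# resample multiplicities; value matrices are subjects x visits with 0 for
# absent visits.
boot_weights <- function(n, n_boot) {
  t(vapply(seq_len(n_boot), function(b) tabulate(sample.int(n, n, replace = TRUE), n),
           integer(n)))
}

arm_visit_matrix <- function(totals, ids, visits, field) {
  m <- matrix(0, length(ids), length(visits),
              dimnames = list(ids, as.character(visits)))
  m[cbind(match(totals$subject_id, ids), match(totals$visit_month, visits))] <-
    totals[[field]]
  m
}

#' Visit-by-arm population-ratio estimates with bootstrap standard errors
#'
#' For every requested outcome, arm and scheduled visit, computes the
#' group-level population-ratio estimate and its bootstrap standard error.
#' Bootstrap resampling draws subjects with replacement within an arm,
#' jointly across visits, so within-subject correlation across visits is
#' preserved; subjects missing a visit are excluded from that visit's
#' estimate (complete-case at the estimation layer -- intent-to-treat
#' handling belongs upstream, via multiple imputation).
#'
#' @param trial A `diet_trial` or a subject-visit totals table from
#'   [visit_totals()] (for `"hba1c"`, the trial's `hba1c` table is used).
#' @param outcomes Character vector of outcomes, see [outcome_names()].
#' @param n_boot Bootstrap resamples per arm (default 5000).
#' @param seed Integer seed.
#' @param standards Standards table for HEI2005.
#' @return Data frame: `outcome`, `arm`, `visit_month`, `estimate`, `se`,
#'   `n_subjects`, `n_bootstrap`, `seed`.
#' @export
estimate_visits <- function(trial, outcomes = c("hei2005", "wpfd"),
                            n_boot = 5000, seed = 1L,
                            standards = hei_standards()) {
  totals <- if (inherits(trial, "diet_trial")) visit_totals(trial) else trial
  res <- list()
  for (outcome in outcomes) {
    def <- outcome_def(outcome)
    tab <- if (def$kind == "mean") {
      if (!inherits(trial, "diet_trial")) stop("hba1c estimation needs a diet_trial")
      h <- trial$hba1c
      h$arm <- trial$subjects$arm[match(h$subject_id, trial$subjects$subject_id)]
      h
    } else totals
    visits <- sort(unique(tab$visit_month))
    for (arm in sort(unique(as.character(tab$arm)))) {
      atab <- tab[tab$arm == arm, , drop = FALSE]
      ids <- unique(atab$subject_id)
      set.seed(seed)
      W <- boot_weights(length(ids), n_boot)
      if (def$kind == "ratio") {
        num <- rowSums(atab[, def$fields, drop = FALSE])
        N <- arm_visit_matrix(cbind(atab, .num = num), ids, visits, ".num")
        E <- arm_visit_matrix(atab, ids, visits, "energy_kcal")
        est <- colSums(N) / colSums(E) * 1000
        boot <- (W %*% N) / (W %*% E) * 1000
      } else if (def$kind == "mean") {
        V <- arm_visit_matrix(cbind(atab, .v = atab$hba1c_pct), ids, visits, ".v")
        P <- arm_visit_matrix(cbind(atab, .one = 1), ids, visits, ".one")
        est <- colSums(V) / colSums(P)
        boot <- (W %*% V) / (W %*% P)
      } else {
        mats <- lapply(diet_fields(), function(f) arm_visit_matrix(atab, ids, visits, f))
        names(mats) <- diet_fields()
        pooled <- as.data.frame(lapply(mats, colSums))
        est <- score_hei2005(pooled, standards)$hei2005_total
        bdf <- as.data.frame(lapply(mats, function(m) as.vector(W %*% m)))
        boot <- matrix(score_hei2005(bdf, standards)$hei2005_total, n_boot, length(visits))
      }
      nsub <- vapply(visits, function(v) sum(atab$visit_month == v), integer(1))
      res[[length(res) + 1L]] <- data.frame(
        outcome = outcome, arm = arm, visit_month = visits,
        estimate = unname(est), se = apply(boot, 2, stats::sd),
        n_subjects = nsub, n_bootstrap = n_boot, seed = seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
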