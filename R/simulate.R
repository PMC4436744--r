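#' Intake-generation profile for the synthetic-trial generator
#'
#' Collects the distributional parameters the generator draws from: mean
#' intake densities (equivalents, g or mg per 1000 kcal) with
#' between-subject and day-to-day SDs, daily energy, moderation-nutrient
#' and macronutrient parameters, HbA1c dynamics, optional per-visit
#' additive density shifts applied to the intervention arm, and the
#' withdrawal schedule.
#'
#' Subject-level mean densities are drawn from a Gamma distribution with
#' the stated mean and between-subject SD (non-negative by construction, so
#' additive intervention shifts move the mean exactly); day-level amounts
#' are subject density times the day's lognormal energy plus additive
#' Gaussian day noise, truncated at zero.
#'
#' @param energy_mean,energy_sd Daily energy intake, kcal.
#' @param density_mean,density_between_sd,density_day_sd Named vectors over
#'   the food-group fields: mean density per 1000 kcal, between-subject SD
#'   of the subject mean density, and day-level additive SD (equivalents
#'   per day).
#' @param satfat_mean,satfat_between_sd,satfat_day_sd Saturated fat,
#'   g/1000 kcal (mean 13.9 corresponds to about 12.5% of energy).
#' @param sodium_mean,sodium_between_sd,sodium_day_sd Sodium, mg/1000 kcal.
#' @param sofaas_pct_mean,sofaas_pct_between_sd,sofaas_pct_day_sd Energy
#'   from solid fats, alcohol and added sugars, percent of energy.
#' @param carb_share_mean,protein_share_mean,share_sd Macronutrient energy
#'   shares (fat takes the remainder).
#' @param hba1c_mean,hba1c_between_sd,hba1c_visit_sd HbA1c percent: overall
#'   mean, between-subject SD and within-subject visit-to-visit SD.
#' @param intervention_shift `NULL` (no treatment effect) or a data frame
#'   with columns `field`, `visit_month`, `shift`: additive change in mean
#'   density (field units per 1000 kcal; for `sofaas_pct`, percentage
#'   points) applied to intervention-arm subjects at that visit.
#' @param withdrawal_schedule `NULL` (no withdrawal) or a data frame with
#'   columns `arm`, `last_month`, `n`: `n` subjects of `arm` withdraw after
#'   their `last_month` visit and contribute no data afterwards.
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(
    energy_mean = 1900, energy_sd = 450,
    density_mean = c(total_fruit = 0.45, whole_fruit = 0.28,
                     total_vegetables = 0.53, dark_green_orange_veg = 0.12,
                     legumes = 0.10, total_grains = 3.4, whole_grains = 0.69,
                     milk = 1.00, meat_beans = 1.70, oils = 6.0,
                     nuts_seeds = 0.07),
    density_between_sd = c(total_fruit = 0.30, whole_fruit = 0.25,
                           total_vegetables = 0.30, dark_green_orange_veg = 0.10,
                           legumes = 0.12, total_grains = 0.80, whole_grains = 0.55,
                           milk = 0.45, meat_beans = 0.60, oils = 2.5,
                           nuts_seeds = 0.08),
    density_day_sd = c(total_fruit = 0.40, whole_fruit = 0.30,
                       total_vegetables = 0.40, dark_green_orange_veg = 0.15,
                       legumes = 0.15, total_grains = 1.20, whole_grains = 0.45,
                       milk = 0.50, meat_beans = 0.90, oils = 3.0,
                       nuts_seeds = 0.12),
    satfat_mean = 13.9, satfat_between_sd = 2.2, satfat_day_sd = 2.0,
    sodium_mean = 1500, sodium_between_sd = 250, sodium_day_sd = 200,
    sofaas_pct_mean = 35, sofaas_pct_between_sd = 7, sofaas_pct_day_sd = 5,
    carb_share_mean = 0.479, protein_share_mean = 0.162, share_sd = 0.02,
    hba1c_mean = 8.1, hba1c_between_sd = 0.94, hba1c_visit_sd = 0.35,
    intervention_shift = NULL,
    withdrawal_schedule = NULL) {
  groups <- setdiff(diet_fields(),
                    c("energy_kcal", "saturated_fat", "sodium", "sofaas_energy",
                      "carbohydrate", "protein", "fat"))
  for (v in list(density_mean, density_between_sd, density_day_sd)) {
    if (!setequal(names(v), groups)) {
      stop("density parameter vectors must be named over: ",
           paste(groups, collapse = ", "))
    }
  }
  sds <- c(energy_sd, density_between_sd, density_day_sd, satfat_between_sd,
           satfat_day_sd, sodium_between_sd, sodium_day_sd,
           sofaas_pct_between_sd, sofaas_pct_day_sd, share_sd,
           hba1c_between_sd, hba1c_visit_sd)
  if (any(sds <= 0)) stop("all SDs must be positive")
  if (energy_mean <= 0) stop("energy mean must be positive")
  if (!is.null(intervention_shift)) {
    need <- c("field", "visit_month", "shift")
    if (!all(need %in% names(intervention_shift))) {
      stop("intervention_shift needs columns field, visit_month, shift")
    }
  }
  if (!is.null(withdrawal_schedule)) {
    need <- c("arm", "last_month", "n")
    if (!all(need %in% names(withdrawal_schedule))) {
      stop("withdrawal_schedule needs columns arm, last_month, n")
    }
  }
  structure(list(
    energy_mean = energy_mean, energy_sd = energy_sd,
    density_mean = density_mean[groups],
    density_between_sd = density_between_sd[groups],
    density_day_sd = density_day_sd[groups],
    satfat_mean = satfat_mean, satfat_between_sd = satfat_between_sd,
    satfat_day_sd = satfat_day_sd,
    sodium_mean = sodium_mean, sodium_between_sd = sodium_between_sd,
    sodium_day_sd = sodium_day_sd,
    sofaas_pct_mean = sofaas_pct_mean,
    sofaas_pct_between_sd = sofaas_pct_between_sd,
    sofaas_pct_day_sd = sofaas_pct_day_sd,
    carb_share_mean = carb_share_mean, protein_share_mean = protein_share_mean,
    share_sd = share_sd,
    hba1c_mean = hba1c_mean, hba1c_between_sd = hba1c_between_sd,
    hba1c_visit_sd = hba1c_visit_sd,
    intervention_shift = intervention_shift,
    withdrawal_schedule = withdrawal_schedule), class = "effect_profile")
}

#' Withdrawal schedule matching the published participant flow
#'
#' Eleven withdrawals out of 136 enrolled, all in the intervention arm:
#' three with baseline data only, three retained through month 3, one
#' through month 6, three through month 9 and one through month 12, giving
#' 92% retention at study completion.
#'
#' @return Data frame with columns `arm`, `last_month`, `n`.
#' @export
study_withdrawal_schedule <- function() {
  data.frame(arm = "treatment",
             last_month = c(0, 3, 6, 9, 12),
             n = c(3, 3, 1, 3, 1),
             stringsAsFactors = FALSE)
}

#' Intervention effect emulating the trial's observed pattern
#'
#' Additive density shifts for the intervention arm that ramp up from month
#' 3 to a full effect at month 18 dominated by whole grains (full-effect
#' WPFD difference 0.5 equivalents/1000 kcal) together with modest
#' improvements in the moderation nutrients, sized so the 18-month HEI2005
#' arm difference is around 7 points.
#'
#' @param visit_months Diet-assessment months carrying an effect.
#' @return Data frame with columns `field`, `visit_month`, `shift`.
#' @export
study_intervention_shift <- function(visit_months = c(3, 6, 9, 12, 18)) {
  full <- c(whole_grains = 0.35, whole_fruit = 0.06, total_fruit = 0.06,
            total_vegetables = 0.05, legumes = 0.02, nuts_seeds = 0.02,
            milk = 0.05, oils = 0.5,
            saturated_fat = -1.0, sodium = -100, sofaas_pct = -4)
  ramp <- stats::approx(c(0, 3, 6, 9, 12, 18), c(0, 0.3, 0.55, 0.75, 0.85, 1),
                        xout = visit_months, rule = 2)$y
  data.frame(field = rep(names(full), each = length(visit_months)),
             visit_month = rep(visit_months, times = length(full)),
             shift = as.vector(outer(ramp, unname(full))),
             stringsAsFactors = FALSE)
}

#' Generation profile calibrated to the study
#'
#' [effect_profile()] defaults plus the study-like intervention effect and
#' the published withdrawal flow.
#'
#' @param ... Overrides passed to [effect_profile()].
#' @return An `effect_profile`.
#' @export
study_effect_profile <- function(...) {
  args <- list(...)
  if (is.null(args$intervention_shift)) args$intervention_shift <- study_intervention_shift()
  if (is.null(args$withdrawal_schedule)) args$withdrawal_schedule <- study_withdrawal_schedule()
  do.call(effect_profile, args)
}

#' Configuration of a synthetic trial
#'
#' @param n_subjects Total enrolment (default 136, as in the study).
#' @param diet_visits Months of the diet-record assessments; the first must
#'   be the baseline month 0.
#' @param hba1c_visits Months of HbA1c measurement (default every 3 months
#'   through month 18).
#' @param block_size Permuted-block size (even; default 4).
#' @param stratum_probs Named probabilities of the younger age band, the
#'   lower HbA1c band and injection (vs pump) regimen, used to sample the
#'   eight randomization strata.
#' @param effect An [effect_profile()]; defaults to the neutral profile
#'   (no intervention effect, no withdrawal).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_subjects = 136,
                         diet_visits = c(0, 3, 6, 9, 12, 18),
                         hba1c_visits = seq(0, 18, by = 3),
                         block_size = 4,
                         stratum_probs = c(age_under13 = 0.5,
                                           hba1c_under8.5 = 0.66,
                                           injection = 0.31),
                         effect = effect_profile()) {
  if (any(diff(diet_visits) <= 0) || any(diff(hba1c_visits) <= 0)) {
    stop("visit months must be strictly increasing")
  }
  if (diet_visits[1] != 0) stop("the first diet visit must be baseline (month 0)")
  if (block_size %% 2 != 0 || block_size < 2) stop("block_size must be a positive even number")
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (!inherits(effect, "effect_profile")) stop("effect must be an effect_profile")
  structure(list(n_subjects = n_subjects, diet_visits = diet_visits,
                 hba1c_visits = hba1c_visits, block_size = block_size,
                 stratum_probs = stratum_probs, effect = effect),
            class = "trial_config")
}

#' Stratified permuted-block randomization
#'
#' Within each stratum, subjects are assigned in enrolment order from
#' consecutive blocks of `block_size`, each block a random permutation of
#' equal counts of the two arms, so the within-stratum arm imbalance never
#' exceeds half a block.
#'
#' @param strata Data frame (or factor/character vector) of stratum labels,
#'   one per subject, in enrolment order. A data frame is collapsed to the
#'   interaction of its columns.
#' @param block_size Even block size.
#' @param seed Integer seed; assignment is a deterministic function of
#'   (strata, block_size, seed). `NULL` uses the current RNG state.
#' @return Character vector of `"treatment"` / `"control"` per subject.
#' @export
assign_randomization <- function(strata, block_size = 4, seed = NULL) {
  if (block_size %% 2 != 0 || block_size < 2) {
    stop("block_size must be even: permuted blocks need equal arm counts per block")
  }
  if (is.data.frame(strata)) {
    strata <- if (nrow(strata) == 0) character(0) else
      do.call(paste, c(strata, sep = "/"))
  }
  n <- length(strata)
  if (n == 0) return(character(0))
  if (!is.null(seed)) set.seed(seed)
  arms <- character(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_blocks <- ceiling(length(idx) / block_size)
    seq_arms <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(c("treatment", "control"), block_size / 2))
    }))
    arms[idx] <- seq_arms[seq_along(idx)]
  }
  arms
}

# truncated-normal subject draw helper (moderation nutrients, shares)
rnorm_pos <- function(n, mean, sd, lower = 0, upper = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

rgamma_meansd <- function(n, mean, sd) {
  stats::rgamma(n, shape = (mean / sd)^2, scale = sd^2 / mean)
}

# per-(field, visit) intervention shift lookup matrix
shift_matrix <- function(shift, fields, visits) {
  m <- matrix(0, length(fields), length(visits),
              dimnames = list(fields, as.character(visits)))
  if (is.null(shift)) return(m)
  unknown <- setdiff(unique(shift$field), c(fields, "saturated_fat", "sodium", "sofaas_pct"))
  if (length(unknown)) stop("unknown shift fields: ", paste(unknown, collapse = ", "))
  keep <- shift$field %in% fields & shift$visit_month %in% visits
  s <- shift[keep, , drop = FALSE]
  m[cbind(match(s$field, fields), match(s$visit_month, visits))] <- s$shift
  m
}

scalar_shift <- function(shift, field, visits) {
  out <- stats::setNames(numeric(length(visits)), as.character(visits))
  if (is.null(shift)) return(out)
  s <- shift[shift$field == field & shift$visit_month %in% visits, , drop = FALSE]
  out[as.character(s$visit_month)] <- s$shift
  out
}

#' Simulate a synthetic randomized nutrition trial
#'
#' Generates a complete trial with the statistical structure the analysis
#' pipeline assumes: stratified permuted-block randomization over the eight
#' age x HbA1c x regimen strata, three record-days of coded intake per
#' subject at each diet-assessment visit, HbA1c at every scheduled HbA1c
#' visit, arm-specific additive density effects, and withdrawal applied per
#' the profile's schedule. Three named random streams (randomization,
#' intake, missingness) are derived from the seed so changing one facet of
#' the simulation does not perturb the others; identical (config, seed)
#' yields an identical dataset.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return Object of class `diet_trial`: a list with data frames `subjects`
#'   (`subject_id`, `arm`, strata, `withdrawal_month`), `diet_days` (one row
#'   per subject x visit x day with the [diet_fields()]), `hba1c`
#'   (`subject_id`, `visit_month`, `hba1c_pct`), plus the `config` and
#'   `seed`.
#' @export
simulate_trial <- function(config = trial_config(), seed = 1L) {
  stopifnot(inherits(config, "trial_config"))
  eff <- config$effect
  n <- config$n_subjects
  visits <- config$diet_visits
  nv <- length(visits)
  groups <- names(eff$density_mean)

  # stream 1: strata and randomization
  set.seed(seed)
  p <- config$stratum_probs
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age_band = ifelse(stats::runif(n) < p[["age_under13"]], "under13", "at_least_13"),
    hba1c_band = ifelse(stats::runif(n) < p[["hba1c_under8.5"]], "under8.5", "at_least_8.5"),
    regimen = ifelse(stats::runif(n) < p[["injection"]], "injection", "pump"),
    stringsAsFactors = FALSE)
  subjects$arm <- assign_randomization(
    subjects[c("age_band", "hba1c_band", "regimen")], config$block_size)
  subjects$withdrawal_month <- NA_real_

  # stream 2: intake and HbA1c
  set.seed(seed + 1L)
  treat <- subjects$arm == "treatment"
  dens_subj <- vapply(groups, function(g) {
    rgamma_meansd(n, eff$density_mean[[g]], eff$density_between_sd[[g]])
  }, numeric(n))
  satfat_subj <- rgamma_meansd(n, eff$satfat_mean, eff$satfat_between_sd)
  sodium_subj <- rgamma_meansd(n, eff$sodium_mean, eff$sodium_between_sd)
  sofaas_subj <- rnorm_pos(n, eff$sofaas_pct_mean, eff$sofaas_pct_between_sd, 2, 90)
  carb_subj <- rnorm_pos(n, eff$carb_share_mean, eff$share_sd, 0.2, 0.7)
  prot_subj <- rnorm_pos(n, eff$protein_share_mean, eff$share_sd, 0.08, 0.35)

  sm <- shift_matrix(eff$intervention_shift, groups, visits)
  satfat_sh <- scalar_shift(eff$intervention_shift, "saturated_fat", visits)
  sodium_sh <- scalar_shift(eff$intervention_shift, "sodium", visits)
  sofaas_sh <- scalar_shift(eff$intervention_shift, "sofaas_pct", visits)

  sdlog <- sqrt(log(1 + (eff$energy_sd / eff$energy_mean)^2))
  meanlog <- log(eff$energy_mean) - sdlog^2 / 2

  n_rows <- n * nv * 3
  days <- data.frame(
    subject_id = rep(subjects$subject_id, each = nv * 3),
    visit_month = rep(rep(visits, each = 3), times = n),
    day_index = rep(1:3, times = n * nv),
    stringsAsFactors = FALSE)
  energy <- stats::rlnorm(n_rows, meanlog, sdlog)
  days$energy_kcal <- energy
  vix <- match(days$visit_month, visits)          # visit index per row
  six <- rep(seq_len(n), each = nv * 3)           # subject index per row
  is_treat <- treat[six]
  # Day noise is additive Gaussian, truncated at 0, with SD proportional to
  # the day's expected amount and equal to density_day_sd at the field's
  # mean density and mean energy; proportional scaling keeps the zero
  # truncation from biasing group means (episodically consumed foods have
  # little day noise near zero intake, which is also the realistic pattern).
  day_noise <- function(expected, sd_at_mean, ref_amount) {
    stats::rnorm(length(expected), 0, sd_at_mean * expected / ref_amount)
  }
  for (g in groups) {
    d <- dens_subj[six, g] + ifelse(is_treat, sm[g, vix], 0)
    d <- pmax(0, d)
    a <- d * energy / 1000
    ref <- eff$density_mean[[g]] * eff$energy_mean / 1000
    days[[g]] <- pmax(0, a + day_noise(a, eff$density_day_sd[[g]], ref))
  }
  satfat_d <- pmax(0, satfat_subj[six] + ifelse(is_treat, satfat_sh[vix], 0))
  a <- satfat_d * energy / 1000
  days$saturated_fat <- pmax(0, a + day_noise(a, eff$satfat_day_sd,
                                              eff$satfat_mean * eff$energy_mean / 1000))
  sodium_d <- pmax(0, sodium_subj[six] + ifelse(is_treat, sodium_sh[vix], 0))
  a <- sodium_d * energy / 1000
  days$sodium <- pmax(0, a + day_noise(a, eff$sodium_day_sd,
                                       eff$sodium_mean * eff$energy_mean / 1000))
  sofaas_p <- pmin(90, pmax(1, sofaas_subj[six] + ifelse(is_treat, sofaas_sh[vix], 0) +
                              stats::rnorm(n_rows, 0, eff$sofaas_pct_day_sd)))
  days$sofaas_energy <- sofaas_p / 100 * energy
  carb <- pmin(0.7, pmax(0.2, carb_subj[six] + stats::rnorm(n_rows, 0, eff$share_sd / 2)))
  prot <- pmin(0.35, pmax(0.08, prot_subj[six] + stats::rnorm(n_rows, 0, eff$share_sd / 2)))
  days$carbohydrate <- carb * energy / 4
  days$protein <- prot * energy / 4
  days$fat <- pmax(0, 1 - carb - prot) * energy / 9
  days <- days[c("subject_id", "visit_month", "day_index", diet_fields())]

  hb_subj <- rnorm_pos(n, eff$hba1c_mean, eff$hba1c_between_sd, 5, 14)
  hvis <- config$hba1c_visits
  hba1c <- data.frame(
    subject_id = rep(subjects$subject_id, each = length(hvis)),
    visit_month = rep(hvis, times = n),
    stringsAsFactors = FALSE)
  hba1c$hba1c_pct <- pmax(4.5, hb_subj[rep(seq_len(n), each = length(hvis))] +
                            stats::rnorm(nrow(hba1c), 0, eff$hba1c_visit_sd))

  trial <- structure(list(subjects = subjects, diet_days = days, hba1c = hba1c,
                          config = config, seed = seed), class = "diet_trial")
  # stream 3: missingness
  if (!is.null(eff$withdrawal_schedule)) {
    trial <- apply_missingness(trial, eff$withdrawal_schedule, seed = seed + 2L)
  }
  trial
}

#' Apply a withdrawal schedule to a simulated trial
#'
#' Marks subjects as withdrawn and removes their diet and HbA1c visits after
#' the last attended month; data before withdrawal are left untouched. A
#' subject withdrawing in the interval `(a, b]` retains visits with month
#' `<= a` (`last_month = a` in the schedule).
#'
#' @param trial A `diet_trial`.
#' @param schedule Data frame with columns `arm`, `last_month`, `n` giving
#'   per-interval withdrawal counts per arm.
#' @param seed Integer seed for choosing which subjects withdraw (`NULL`
#'   uses the current RNG state).
#' @return The trial with `withdrawal_month` set and later visits removed.
#' @export
apply_missingness <- function(trial, schedule, seed = NULL) {
  stopifnot(inherits(trial, "diet_trial"))
  if (!all(c("arm", "last_month", "n") %in% names(schedule))) {
    stop("schedule needs columns arm, last_month, n")
  }
  if (!is.null(seed)) set.seed(seed)
  subj <- trial$subjects
  for (arm in unique(schedule$arm)) {
    want <- sum(schedule$n[schedule$arm == arm])
    have <- sum(subj$arm == arm & is.na(subj$withdrawal_month))
    if (want > have) {
      stop("schedule requests ", want, " withdrawals from arm '", arm,
           "' but only ", have, " subjects are available")
    }
  }
  sched <- schedule[schedule$n > 0, , drop = FALSE]
  sched <- sched[order(sched$last_month), , drop = FALSE]
  for (i in seq_len(nrow(sched))) {
    pool <- which(subj$arm == sched$arm[i] & is.na(subj$withdrawal_month))
    pick <- pool[sample.int(length(pool), sched$n[i])]
    subj$withdrawal_month[pick] <- sched$last_month[i]
  }
  wd <- subj$withdrawal_month[match(trial$diet_days$subject_id, subj$subject_id)]
  keep_d <- is.na(wd) | trial$diet_days$visit_month <= wd
  wh <- subj$withdrawal_month[match(trial$hba1c$subject_id, subj$subject_id)]
  keep_h <- is.na(wh) | trial$hba1c$visit_month <= wh
  trial$subjects <- subj
  trial$diet_days <- trial$diet_days[keep_d, , drop = FALSE]
  trial$hba1c <- trial$hba1c[keep_h, , drop = FALSE]
  rownames(trial$diet_days) <- rownames(trial$hba1c) <- NULL
  trial
}

#' Proportion of subjects retained through study completion
#'
#' @param trial A `diet_trial`.
#' @return Fraction of enrolled subjects never withdrawn.
#' @export
retention <- function(trial) {
  mean(is.na(trial$subjects$withdrawal_month))
}

#' @export
print.diet_trial <- function(x, ...) {
  n <- nrow(x$subjects)
  cat("Synthetic randomized nutrition trial\n")
  cat(sprintf("  %d subjects (%d treatment / %d control), %d withdrawn (retention %.1f%%)\n",
              n, sum(x$subjects$arm == "treatment"),
              sum(x$subjects$arm == "control"),
              sum(!is.na(x$subjects$withdrawal_month)), 100 * retention(x)))
  cat(sprintf("  diet visits at months %s (3 record-days each), %d day-records\n",
              paste(x$config$diet_visits, collapse = ", "), nrow(x$diet_days)))
  cat(sprintf("  HbA1c at months %s, %d measurements\n",
              paste(x$config$hba1c_visits, collapse = ", "), nrow(x$hba1c)))
  invisible(x)
}
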