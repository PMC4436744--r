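# Fixture builders and independent oracles used across the test files.

# one record-day (or totals row) with every field zero except overrides
mk_day <- function(energy_kcal = 2000, ...) {
  row <- as.data.frame(as.list(stats::setNames(numeric(length(diet_fields())),
                                               diet_fields())))
  row$energy_kcal <- energy_kcal
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# intake meeting every adequacy standard with all moderation nutrients in
# the full-credit range (2000 kcal)
perfect_day <- function() {
  mk_day(energy_kcal = 2000, total_fruit = 1.6, whole_fruit = 0.8,
         total_vegetables = 2.2, dark_green_orange_veg = 0.8,
         total_grains = 6, whole_grains = 3, milk = 2.6, meat_beans = 5,
         oils = 24, saturated_fat = 15, sodium = 1400, sofaas_energy = 300,
         carbohydrate = 240, protein = 80, fat = 70)
}

# zero intake of all adequacy groups, moderation nutrients at/beyond the
# zero-credit thresholds
worst_day <- function() {
  mk_day(energy_kcal = 2000, saturated_fat = 36, sodium = 4100,
         sofaas_energy = 1100, fat = 80)
}

# random valid intake totals for property checks
random_intakes <- function(n, seed = 1) {
  set.seed(seed)
  e <- stats::runif(n, 1000, 3500)
  data.frame(
    energy_kcal = e,
    total_fruit = stats::runif(n, 0, 4), whole_fruit = stats::runif(n, 0, 3),
    total_vegetables = stats::runif(n, 0, 5),
    dark_green_orange_veg = stats::runif(n, 0, 2),
    legumes = stats::runif(n, 0, 2), total_grains = stats::runif(n, 0, 12),
    whole_grains = stats::runif(n, 0, 6), milk = stats::runif(n, 0, 5),
    meat_beans = stats::runif(n, 0, 8), oils = stats::runif(n, 0, 40),
    saturated_fat = stats::runif(n, 0, 45), sodium = stats::runif(n, 0, 7000),
    sofaas_energy = stats::runif(n, 0, 0.6) * e,
    nuts_seeds = stats::runif(n, 0, 1.5),
    carbohydrate = stats::runif(n, 50, 400), protein = stats::runif(n, 20, 150),
    fat = stats::runif(n, 20, 120))
}

# independent branchy implementation of the moderation score (oracle for
# the interpolation-based scorer)
oracle_moderation <- function(density, maxp, full, mid_x, mid_pts, zero) {
  vapply(density, function(d) {
    if (d <= full) return(maxp)
    if (d >= zero) return(0)
    if (!is.na(mid_x)) {
      if (d <= mid_x) {
        maxp + (mid_pts - maxp) * (d - full) / (mid_x - full)
      } else {
        mid_pts * (zero - d) / (zero - mid_x)
      }
    } else {
      maxp * (zero - d) / (zero - full)
    }
  }, numeric(1))
}

# small complete analysis table for ratio outcomes: n subjects per arm,
# visits as given, fields whole_grains (numerator) and energy
mk_ratio_table <- function(n_per_arm, visits = c(0, 6), seed = 1) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(2 * n_per_arm))
  arm <- rep(c("treatment", "control"), each = n_per_arm)
  rows <- expand.grid(subject_id = ids, visit_month = visits,
                      stringsAsFactors = FALSE)
  rows$arm <- arm[match(rows$subject_id, ids)]
  base <- mk_day(energy_kcal = 1)[rep(1, nrow(rows)), ]
  rownames(base) <- NULL
  rows <- cbind(rows, base)
  rows$energy_kcal <- stats::runif(nrow(rows), 4000, 8000)
  rows$whole_grains <- stats::runif(nrow(rows), 0, 8)
  rows$n_days <- 3
  rows
}

# exact permutation p-value for a ratio outcome by exhaustive enumeration,
# computed with plain loops independent of the package's matrix path
exact_perm_p <- function(tab, numerator = "whole_grains") {
  ids <- unique(tab$subject_id)
  visits <- sort(unique(tab$visit_month))
  n1 <- length(unique(tab$subject_id[tab$arm == "treatment"]))
  vec <- function(members) {
    sapply(visits, function(v) {
      rows <- tab[tab$visit_month == v & tab$subject_id %in% members, ]
      sum(rows[[numerator]]) / sum(rows$energy_kcal) * 1000
    })
  }
  dist_for <- function(members) {
    others <- setdiff(ids, members)
    sqrt(sum((vec(members) - vec(others))^2))
  }
  obs <- dist_for(unique(tab$subject_id[tab$arm == "treatment"]))
  splits <- utils::combn(ids, n1)
  dists <- apply(splits, 2, dist_for)
  list(observed = obs, p = mean(dists >= obs - 1e-12))
}

# default-profile trial config without any intervention effect/withdrawal
null_config <- function(n = 136, visits = c(0, 3, 6, 9, 12, 18)) {
  trial_config(n_subjects = n, diet_visits = visits,
               hba1c_visits = if (length(visits) > 1) seq(0, 18, 3) else 0,
               effect = effect_profile())
}
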