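#' Aggregate a multi-day food record into one set of intake totals
#'
#' Sums the record-days of one subject-visit field-wise. Scoring and density
#' estimation operate on these totals (not on day-by-day scores), matching
#' how densities are estimated from short-term records.
#'
#' @param days Data frame of record-days, one row per day, containing every
#'   field of [diet_fields()].
#' @return One-row data frame of field-wise totals plus `n_days`.
#' @export
aggregate_record <- function(days) {
  if (!is.data.frame(days) || nrow(days) == 0) {
    stop("at least one record-day is required")
  }
  flds <- diet_fields()
  missing <- setdiff(flds, names(days))
  if (length(missing)) {
    stop("record-days are missing fields: ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(days[flds])))) {
    stop("record-day fields must be finite numbers")
  }
  if (any(days$energy_kcal <= 0)) stop("every record-day must have energy_kcal > 0")
  if (any(as.matrix(days[flds]) < 0)) stop("record-day amounts must be non-negative")
  totals <- as.data.frame(as.list(colSums(days[flds])))
  totals$n_days <- nrow(days)
  totals
}

#' Credit legumes to the meat-and-beans component, remainder to vegetables
#'
#' HEI2005 allocation rule: legume intake counts toward the meat-and-beans
#' component (at 4 oz-eq per cup-eq) until that component's density standard
#' is met; any remaining legume cup-equivalents are credited, one-for-one,
#' to total vegetables and to the dark-green/orange-vegetables-and-legumes
#' component. The input is not modified.
#'
#' @param totals Data frame of intake totals (one or more rows).
#' @param standards Standards table from [hei_standards()].
#' @return Adjusted copy of `totals` used for component scoring.
#' @export
allocate_legumes <- function(totals, standards = hei_standards()) {
  adj <- totals
  meat_std <- standards$standard[standards$component == "meat_beans"]
  # oz-eq still needed to reach the meat standard at this energy intake
  need_oz <- pmax(0, meat_std * adj$energy_kcal / 1000 - adj$meat_beans)
  to_meat_cup <- pmin(adj$legumes, need_oz / 4)
  remainder <- adj$legumes - to_meat_cup
  adj$meat_beans <- adj$meat_beans + 4 * to_meat_cup
  adj$total_vegetables <- adj$total_vegetables + remainder
  adj$dark_green_orange_veg <- adj$dark_green_orange_veg + remainder
  adj
}

#' Score one HEI2005 component from its intake density
#'
#' Adequacy components score `max_points * density / standard`, truncated at
#' the maximum. Moderation components score piecewise-linearly from the
#' maximum at the full-credit threshold, through the optional intermediate
#' anchor, to zero at the zero-credit threshold; densities at a threshold
#' score the boundary value exactly.
#'
#' @param density Numeric vector of densities (per 1000 kcal or percent of
#'   energy, in the component's units).
#' @param spec One row of the standards table.
#' @return Numeric vector of points in `[0, max_points]`.
#' @export
score_component <- function(density, spec) {
  if (any(density < 0)) stop("densities must be non-negative")
  maxp <- spec$max_points
  if (spec$orientation == "adequacy") {
    return(pmin(maxp, maxp * density / spec$standard))
  }
  xs <- c(spec$standard, spec$mid_value, spec$zero_value)
  ys <- c(maxp, spec$mid_points, 0)
  keep <- !is.na(xs)
  stats::approx(xs[keep], ys[keep], xout = density, rule = 2)$y
}

# densities for every component, in each component's own units
component_densities <- function(totals, standards) {
  e <- totals$energy_kcal
  dens <- matrix(NA_real_, nrow(totals), nrow(standards),
                 dimnames = list(NULL, standards$component))
  for (i in seq_len(nrow(standards))) {
    amount <- totals[[standards$numerator[i]]] * standards$scale[i]
    dens[, i] <- if (standards$basis[i] == "pct_energy") {
      amount / e * 100
    } else {
      amount / e * 1000
    }
  }
  dens
}

#' Compute HEI2005 component and total scores
#'
#' Applies the legume allocation, converts intake totals into per-1000-kcal
#' (or percent-of-energy) densities, scores the 12 components and sums them
#' into the 0-100 total. Vectorised over rows, so a data frame of
#' subject-visit totals yields one score row per input row.
#'
#' @param totals Data frame of intake totals (e.g. from
#'   [aggregate_record()]), one row per subject-visit.
#' @param standards Standards table from [hei_standards()].
#' @return Data frame with one column per component plus `hei2005_total`.
#' @export
score_hei2005 <- function(totals, standards = hei_standards()) {
  if (!is.data.frame(totals) || nrow(totals) == 0) stop("totals must be a non-empty data frame")
  if (any(totals$energy_kcal <= 0)) stop("energy total must be positive")
  adj <- allocate_legumes(totals, standards)
  dens <- component_densities(adj, standards)
  scores <- dens
  for (i in seq_len(nrow(standards))) {
    scores[, i] <- score_component(dens[, i], standards[i, ])
  }
  out <- as.data.frame(scores)
  out$hei2005_total <- rowSums(scores)
  out
}

#' Whole Plant Food Density
#'
#' Cup/ounce equivalents of whole grains, whole fruit, vegetables, legumes,
#' nuts and seeds consumed per 1000 kcal of total energy.
#'
#' @param totals Data frame of intake totals; vectorised over rows.
#' @return Numeric vector of densities (equivalents per 1000 kcal).
#' @export
compute_wpfd <- function(totals) {
  if (any(totals$energy_kcal <= 0)) stop("energy total must be positive")
  with(totals,
       (whole_grains + whole_fruit + total_vegetables + legumes + nuts_seeds) /
         energy_kcal * 1000)
}
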