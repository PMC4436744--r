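#' Column names of a coded diet-record day
#'
#' The canonical numeric fields of one record-day of coded intake: total
#' energy, food-group cup/ounce equivalents, moderation nutrients, and
#' macronutrient grams. All amounts are per day; densities (per 1000 kcal)
#' are derived downstream.
#'
#' @return Character vector of field names, starting with `energy_kcal`.
#' @export
diet_fields <- function() {
  c("energy_kcal",
    "total_fruit", "whole_fruit",
    "total_vegetables", "dark_green_orange_veg", "legumes",
    "total_grains", "whole_grains",
    "milk", "meat_beans", "oils",
    "saturated_fat", "sodium", "sofaas_energy",
    "nuts_seeds", "carbohydrate", "protein", "fat")
}

#' HEI2005 component scoring standards
#'
#' Loads the scoring standards for the 12 components of the Healthy Eating
#' Index 2005. Each component is either an *adequacy* component (score rises
#' linearly with intake density up to a full-credit standard, then is
#' truncated at the component maximum) or a *moderation* component (score
#' falls piecewise-linearly from the maximum at a full-credit threshold,
#' through an optional intermediate anchor, to zero at a zero-credit
#' threshold). Densities are expressed per 1000 kcal or as percent of
#' energy; the `scale` column converts raw field units into the standard's
#' units (9 kcal/g for saturated fat, mg to g for sodium).
#'
#' The standards ship as an editable CSV so alternative index versions can
#' be plugged in; the defaults are the published HEI2005 standards.
#'
#' @param path Optional path to an alternative standards CSV with the same
#'   columns as the shipped file.
#' @return A data frame with one row per component and columns `component`,
#'   `orientation`, `max_points`, `numerator`, `basis`, `scale`, `standard`,
#'   `mid_value`, `mid_points`, `zero_value`.
#' @export
hei_standards <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hei2005_standards.csv",
                        package = "dietquality", mustWork = TRUE)
  }
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("component", "orientation", "max_points", "numerator",
                "basis", "scale", "standard", "mid_value", "mid_points",
                "zero_value")
  missing <- setdiff(required, names(std))
  if (length(missing)) {
    stop("standards file is missing columns: ", paste(missing, collapse = ", "))
  }
  if (sum(std$max_points) != 100) {
    stop("component maxima must sum to 100 points, got ", sum(std$max_points))
  }
  if (any(std$orientation == "adequacy" & std$standard <= 0)) {
    stop("adequacy full-credit standards must be positive")
  }
  mod <- std[std$orientation == "moderation", ]
  bad <- with(mod, standard >= zero_value |
                (!is.na(mid_value) & (mid_value <= standard | mid_value >= zero_value)))
  if (any(bad)) stop("moderation thresholds must be strictly ordered")
  std
}
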