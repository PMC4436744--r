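#' Write a trial dataset as plain CSV files
#'
#' Writes `subjects.csv`, `diet_days.csv` and `hba1c.csv` (RFC-4180, UTF-8,
#' '.' decimal) plus the column dictionary as `columns.json` into a
#' directory.
#'
#' @param trial A `diet_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "diet_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(trial$diet_days, file.path(dir, "diet_days.csv"), row.names = FALSE)
  utils::write.csv(trial$hba1c, file.path(dir, "hba1c.csv"), row.names = FALSE)
  file.copy(system.file("extdata", "column_dictionary.json",
                        package = "dietquality", mustWork = TRUE),
            file.path(dir, "columns.json"), overwrite = TRUE)
  invisible(dir)
}

check_numeric <- function(df, cols, file, errors) {
  for (cl in cols) {
    bad <- which(!is.na(df[[cl]]) & is.na(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad)) {
      errors[[length(errors) + 1L]] <- sprintf(
        "%s: non-numeric values in column '%s' at row(s) %s",
        file, cl, paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  errors
}

#' Read and validate a trial dataset from CSV files
#'
#' Reads the three canonical CSVs and checks the dataset invariants:
#' required columns, numeric cells, positive energy, non-negative amounts,
#' no duplicate (subject, visit, day) keys, and that every diet/HbA1c row
#' refers to a known subject. Violations are reported together, each naming
#' the file, column and row concerned.
#'
#' @param dir Directory holding `subjects.csv`, `diet_days.csv`,
#'   `hba1c.csv`; alternatively pass the three paths explicitly.
#' @param subjects,diet_days,hba1c Optional explicit file paths.
#' @param diet_visits,hba1c_visits Visit schedules to record in the
#'   reconstructed config; defaults are inferred from the data.
#' @return A `diet_trial`.
#' @export
read_trial <- function(dir = NULL, subjects = NULL, diet_days = NULL,
                       hba1c = NULL, diet_visits = NULL, hba1c_visits = NULL) {
  if (!is.null(dir)) {
    subjects <- subjects %||% file.path(dir, "subjects.csv")
    diet_days <- diet_days %||% file.path(dir, "diet_days.csv")
    hba1c <- hba1c %||% file.path(dir, "hba1c.csv")
  }
  for (f in c(subjects, diet_days, hba1c)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  subj <- utils::read.csv(subjects, stringsAsFactors = FALSE)
  days <- utils::read.csv(diet_days, stringsAsFactors = FALSE, colClasses = "character")
  hb <- utils::read.csv(hba1c, stringsAsFactors = FALSE, colClasses = "character")

  errors <- list()
  need_s <- c("subject_id", "arm", "withdrawal_month")
  need_d <- c("subject_id", "visit_month", "day_index", diet_fields())
  need_h <- c("subject_id", "visit_month", "hba1c_pct")
  for (spec in list(list(subj, need_s, "subjects.csv"),
                    list(days, need_d, "diet_days.csv"),
                    list(hb, need_h, "hba1c.csv"))) {
    missing <- setdiff(spec[[2]], names(spec[[1]]))
    if (length(missing)) {
      errors[[length(errors) + 1L]] <- sprintf(
        "%s: missing column(s) %s", spec[[3]], paste(missing, collapse = ", "))
    }
  }
  if (length(errors)) stop(paste(unlist(errors), collapse = "\n"))

  errors <- check_numeric(days, c("visit_month", "day_index", diet_fields()),
                          "diet_days.csv", errors)
  errors <- check_numeric(hb, c("visit_month", "hba1c_pct"), "hba1c.csv", errors)
  if (!length(errors)) {
    for (cl in c("visit_month", "day_index", diet_fields())) {
      days[[cl]] <- as.numeric(days[[cl]])
    }
    hb$visit_month <- as.numeric(hb$visit_month)
    hb$hba1c_pct <- as.numeric(hb$hba1c_pct)

    bad <- which(days$energy_kcal <= 0)
    if (length(bad)) {
      errors[[length(errors) + 1L]] <- sprintf(
        "diet_days.csv: non-positive energy_kcal at row(s) %s",
        paste(utils::head(bad, 5), collapse = ", "))
    }
    for (cl in setdiff(diet_fields(), "energy_kcal")) {
      bad <- which(days[[cl]] < 0)
      if (length(bad)) {
        errors[[length(errors) + 1L]] <- sprintf(
          "diet_days.csv: negative values in column '%s' at row(s) %s",
          cl, paste(utils::head(bad, 5), collapse = ", "))
      }
    }
    key <- paste(days$subject_id, days$visit_month, days$day_index)
    dup <- unique(key[duplicated(key)])
    if (length(dup)) {
      errors[[length(errors) + 1L]] <- sprintf(
        "diet_days.csv: duplicate (subject, visit, day) key(s): %s",
        paste(utils::head(dup, 5), collapse = "; "))
    }
    orphan <- unique(c(setdiff(days$subject_id, subj$subject_id),
                       setdiff(hb$subject_id, subj$subject_id)))
    if (length(orphan)) {
      errors[[length(errors) + 1L]] <- sprintf(
        "diet/hba1c rows reference unknown subject(s): %s",
        paste(utils::head(orphan, 5), collapse = ", "))
    }
  }
  if (length(errors)) stop(paste(unlist(errors), collapse = "\n"))

  subj$withdrawal_month <- suppressWarnings(as.numeric(subj$withdrawal_month))
  dv <- diet_visits %||% sort(unique(days$visit_month))
  hv <- hba1c_visits %||% sort(unique(hb$visit_month))
  cfg <- trial_config(n_subjects = max(2, nrow(subj)), diet_visits = dv,
                      hba1c_visits = hv)
  structure(list(subjects = subj, diet_days = days, hba1c = hb,
                 config = cfg, seed = NA_integer_), class = "diet_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
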