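#' Write a cohort to CSV
#'
#' Writes `knees.csv` (one row per knee) and `visits.csv` (one row per
#' knee-visit) with fixed, documented headers. Missing values are encoded as
#' empty fields; logical flags as TRUE/FALSE. The pair of files round-trips
#' losslessly through [read_cohort_csv()].
#'
#' @param cohort A [vkr_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vkr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  knees_path <- file.path(dir, "knees.csv")
  visits_path <- file.path(dir, "visits.csv")
  utils::write.csv(cohort$knees, knees_path, row.names = FALSE, na = "")
  utils::write.csv(cohort$visits, visits_path, row.names = FALSE, na = "")
  invisible(c(knees = knees_path, visits = visits_path))
}

#' Read a cohort from CSV
#'
#' Reads the `knees.csv`/`visits.csv` pair written by [write_cohort_csv()],
#' validating the headers, rejecting unknown thickness columns and duplicate
#' (knee, month) rows, and restoring column types.
#'
#' @param dir Directory containing `knees.csv` and `visits.csv`.
#' @return A [vkr_cohort()].
#' @export
read_cohort_csv <- function(dir) {
  knees_path <- file.path(dir, "knees.csv")
  visits_path <- file.path(dir, "visits.csv")
  for (p in c(knees_path, visits_path)) {
    if (!file.exists(p)) stop("missing cohort file: ", p)
  }
  knees <- utils::read.csv(knees_path, stringsAsFactors = FALSE, na.strings = "")
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE, na.strings = "")
  missing_k <- setdiff(knee_columns(), names(knees))
  if (length(missing_k)) {
    stop("knees.csv lacks column(s): ", paste(missing_k, collapse = ", "))
  }
  missing_v <- setdiff(visit_columns(), names(visits))
  if (length(missing_v)) {
    stop("visits.csv lacks column(s): ", paste(missing_v, collapse = ", "))
  }
  th_cols <- grep("^th_", names(visits), value = TRUE)
  unknown <- setdiff(th_cols, thickness_columns())
  if (length(unknown)) {
    stop("unknown subregion column(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(visits) > 0L) {
    dup <- duplicated(visits[, c("knee_id", "visit_month")])
    if (any(dup)) {
      d <- visits[dup, , drop = FALSE][1L, ]
      stop("duplicate visit row for knee ", d$knee_id, " at month ", d$visit_month)
    }
  }
  # restore types that read.csv may have degraded on empty/all-NA columns
  knees$surgical_kr_month <- as.integer(knees$surgical_kr_month)
  knees$klg <- as.integer(knees$klg)
  for (cl in c("continuous_coverage", "symptom_progressor", "structure_case")) {
    knees[[cl]] <- as.logical(knees[[cl]])
  }
  visits$visit_month <- as.integer(visits$visit_month)
  visits$pro_present <- as.logical(visits$pro_present)
  visits$cart_readable <- as.logical(visits$cart_readable)
  for (cl in c("koos_pain", "koos_qol", "womac_pain", "bmi",
               thickness_columns(), "mjsw_medial")) {
    visits[[cl]] <- as.numeric(visits[[cl]])
  }
  vkr_cohort(knees, visits)
}
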