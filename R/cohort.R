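#' Scheduled visit months
#'
#' Annual visits at months 0 through 72, matching the OAI-style follow-up
#' schedule the analysis assumes.
#'
#' @return Integer vector `c(0, 12, 24, 36, 48, 60, 72)`.
#' @export
vkr_visit_months <- function() as.integer(seq(0L, 72L, by = 12L))

#' Construct a knee cohort
#'
#' A cohort is a pair of rectangular tables. `knees` has one row per knee:
#' identifiers, demographics, baseline radiographic status (Kellgren-Lawrence
#' grade and per-compartment joint-space-narrowing grades), surgical knee
#' replacement month (NA if none) and a continuous health-coverage flag.
#' `visits` has one row per knee and scheduled month: patient-reported
#' outcomes (KOOS pain, KOOS quality of life, WOMAC pain), BMI, the 16
#' subregion cartilage thickness values (micrometres, columns `th_*`), the
#' minimal medial joint-space width (mm) and per-visit presence/readability
#' flags.
#'
#' @param knees Data frame of per-knee rows.
#' @param visits Data frame of per-knee-visit rows.
#' @param n_clipped Number of KOOS values clipped to the 0-100 bounds during
#'   simulation (0 for data read from file).
#' @return Object of class `vkr_cohort`.
#' @export
vkr_cohort <- function(knees, visits, n_clipped = 0L) {
  obj <- structure(
    list(knees = knees, visits = visits, n_clipped = as.integer(n_clipped)),
    class = "vkr_cohort"
  )
  validate_cohort(obj)
  obj
}

knee_columns <- function() {
  c(
    "knee_id", "participant_id", "side", "sex", "age_baseline",
    "klg", "klg_stratum", "jsn_medial", "jsn_lateral", "jsn_dominant",
    "surgical_kr_month", "continuous_coverage",
    "symptom_progressor", "structure_case", "latent_symptom", "latent_structure"
  )
}

visit_columns <- function() {
  c(
    "knee_id", "visit_month", "pro_present", "koos_pain", "koos_qol",
    "womac_pain", "bmi", "cart_readable", thickness_columns(), "mjsw_medial"
  )
}

validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort$knees), is.data.frame(cohort$visits))
  missing_k <- setdiff(knee_columns(), names(cohort$knees))
  if (length(missing_k) > 0L) {
    stop("knees table lacks column(s): ", paste(missing_k, collapse = ", "))
  }
  missing_v <- setdiff(visit_columns(), names(cohort$visits))
  if (length(missing_v) > 0L) {
    stop("visits table lacks column(s): ", paste(missing_v, collapse = ", "))
  }
  if (nrow(cohort$visits) > 0L) {
    if (anyDuplicated(cohort$visits[, c("knee_id", "visit_month")])) {
      stop("duplicate (knee_id, visit_month) rows in visits table")
    }
    if (!all(cohort$visits$visit_month %in% vkr_visit_months())) {
      stop("visit_month outside the scheduled months 0,12,...,72")
    }
    kp <- cohort$visits$koos_pain
    ql <- cohort$visits$koos_qol
    if (any(kp < 0 | kp > 100, na.rm = TRUE) || any(ql < 0 | ql > 100, na.rm = TRUE)) {
      stop("KOOS scores outside [0, 100]")
    }
  }
  if (anyDuplicated(cohort$knees$knee_id)) stop("duplicate knee_id in knees table")
  invisible(cohort)
}

#' @export
print.vkr_cohort <- function(x, ...) {
  cat(sprintf(
    "<vkr_cohort> %d knees, %d participants, %d visit rows (%d KOOS values clipped)\n",
    nrow(x$knees), length(unique(x$knees$participant_id)), nrow(x$visits),
    x$n_clipped
  ))
  invisible(x)
}

empty_cohort <- function() {
  knees <- as.data.frame(
    c(
      list(
        knee_id = character(), participant_id = character(),
        side = character(), sex = character(), age_baseline = numeric(),
        klg = integer(), klg_stratum = character(),
        jsn_medial = integer(), jsn_lateral = integer(),
        jsn_dominant = character(), surgical_kr_month = integer(),
        continuous_coverage = logical(), symptom_progressor = logical(),
        structure_case = logical(), latent_symptom = numeric(),
        latent_structure = numeric()
      )
    ),
    stringsAsFactors = FALSE
  )
  vis_list <- c(
    list(
      knee_id = character(), visit_month = integer(), pro_present = logical(),
      koos_pain = numeric(), koos_qol = numeric(), womac_pain = numeric(),
      bmi = numeric(), cart_readable = logical()
    ),
    stats::setNames(rep(list(numeric()), 16L), thickness_columns()),
    list(mjsw_medial = numeric())
  )
  vkr_cohort(knees, as.data.frame(vis_list, stringsAsFactors = FALSE))
}

#' Extract one knee's longitudinal series
#'
#' @param cohort A `vkr_cohort`.
#' @param knee_id Single knee identifier.
#' @return Object of class `knee_series` with elements `info` (the knee row)
#'   and `visits` (that knee's visit rows ordered by month).
#' @export
knee_series <- function(cohort, knee_id) {
  stopifnot(inherits(cohort, "vkr_cohort"), length(knee_id) == 1L)
  i <- which(cohort$knees$knee_id == knee_id)
  if (length(i) != 1L) stop("unknown knee_id: ", knee_id)
  v <- cohort$visits[cohort$visits$knee_id == knee_id, , drop = FALSE]
  v <- v[order(v$visit_month), , drop = FALSE]
  structure(list(info = cohort$knees[i, , drop = FALSE], visits = v),
            class = "knee_series")
}

# map KL grade to the matching stratum used for matching (0/1 pooled)
klg_to_stratum <- function(klg) {
  out <- rep(NA_character_, length(klg))
  out[!is.na(klg) & klg <= 1] <- "0-1"
  out[!is.na(klg) & klg == 2] <- "2"
  out[!is.na(klg) & klg == 3] <- "3"
  out[!is.na(klg) & klg == 4] <- "4"
  out
}

# dominant joint-space-narrowing compartment from the two grades
jsn_dominant_compartment <- function(jsn_medial, jsn_lateral) {
  out <- rep(NA_character_, length(jsn_medial))
  ok <- !is.na(jsn_medial) & !is.na(jsn_lateral)
  out[ok & jsn_medial == 0 & jsn_lateral == 0] <- "none"
  out[ok & jsn_medial == jsn_lateral & jsn_medial > 0] <- "both"
  out[ok & jsn_medial > jsn_lateral] <- "medial"
  out[ok & jsn_medial < jsn_lateral] <- "lateral"
  out
}

# contralateral knee id within the same participant, NA when absent
contralateral_ids <- function(knees) {
  other <- ifelse(knees$side == "L", "R", "L")
  key <- paste(knees$participant_id, other, sep = "|")
  lookup <- stats::setNames(knees$knee_id, paste(knees$participant_id, knees$side, sep = "|"))
  unname(lookup[key])
}
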