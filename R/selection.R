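#' Apply the eligibility exclusion cascade
#'
#' Removes knees in a fixed, audited order: (1) surgical knee replacement
#' before 12 months, (2) no 12-month follow-up PRO visit, (3) no continuous
#' health coverage, (4) insufficient KOOS data (baseline KOOS pain/QOL not
#' recorded), and (5) no central baseline Kellgren-Lawrence reading. A knee
#' removed at one step is not counted again at later steps, so the counts
#' reconcile exactly: initial n minus the removals equals the eligible n.
#'
#' @param cohort A [vkr_cohort()].
#' @param target_month Analysis month the cascade feeds (kept for the run
#'   manifest; the steps themselves are fixed).
#' @return Object of class `cascade_report`: `steps` (data frame with
#'   `step`, `n_removed`, `n_remaining`), `eligible` (knee ids), `n_initial`.
#' @export
apply_exclusion_cascade <- function(cohort, target_month = 60L) {
  stopifnot(inherits(cohort, "vkr_cohort"))
  k <- cohort$knees
  v <- cohort$visits
  n0 <- nrow(k)
  pro12 <- v[v$visit_month == 12L, , drop = FALSE]
  has_12m <- k$knee_id %in% pro12$knee_id[pro12$pro_present]
  pro0 <- v[v$visit_month == 0L, , drop = FALSE]
  koos0_ok <- k$knee_id %in% pro0$knee_id[
    pro0$pro_present & !is.na(pro0$koos_pain) & !is.na(pro0$koos_qol)
  ]
  reasons <- list(
    "surgical KR before 12 M" = !is.na(k$surgical_kr_month) & k$surgical_kr_month < 12L,
    "no 12 M follow-up" = !has_12m,
    "no continuous health coverage" = !k$continuous_coverage,
    "insufficient KOOS data" = !koos0_ok,
    "no baseline KL grade reading" = is.na(k$klg)
  )
  alive <- rep(TRUE, n0)
  steps <- data.frame(
    step = names(reasons), n_removed = NA_integer_, n_remaining = NA_integer_,
    stringsAsFactors = FALSE
  )
  removed_ids <- list()
  for (i in seq_along(reasons)) {
    hit <- alive & reasons[[i]]
    removed_ids[[names(reasons)[i]]] <- k$knee_id[hit]
    alive <- alive & !hit
    steps$n_removed[i] <- sum(hit)
    steps$n_remaining[i] <- sum(alive)
  }
  new_cascade_report(steps, eligible = k$knee_id[alive], n_initial = n0,
                     removed_ids = removed_ids)
}

#' Construct a cascade report
#'
#' Builds (and validates) the step-by-step accounting object that
#' [apply_exclusion_cascade()] returns; exposed so that externally reported
#' exclusion counts can be checked with the same arithmetic.
#'
#' @param steps Data frame with `step`, `n_removed`, `n_remaining`.
#' @param eligible Character vector of eligible knee ids (optional).
#' @param n_initial Initial number of knees.
#' @param removed_ids Optional named list of removed ids per step.
#' @return Object of class `cascade_report`.
#' @export
#' @examples
#' # reported counts reconcile: 9592 knees minus five removals leaves 8205
#' rep <- new_cascade_report(
#'   data.frame(step = c("KR before 12 M", "no 12 M follow-up", "no coverage",
#'                       "insufficient KOOS", "no baseline KLG"),
#'              n_removed = c(92, 590, 483, 44, 178),
#'              n_remaining = 9592 - cumsum(c(92, 590, 483, 44, 178))),
#'   n_initial = 9592)
#' tail(rep$steps$n_remaining, 1)
new_cascade_report <- function(steps, eligible = character(), n_initial,
                               removed_ids = list()) {
  stopifnot(is.data.frame(steps),
            all(c("step", "n_removed", "n_remaining") %in% names(steps)))
  if (any(steps$n_removed < 0) || any(steps$n_remaining < 0)) {
    stop("cascade counts must be non-negative")
  }
  expected <- n_initial - cumsum(steps$n_removed)
  if (!all(steps$n_remaining == expected)) {
    stop("cascade counts do not reconcile: n_remaining must decrease by n_removed")
  }
  structure(
    list(steps = steps, eligible = eligible, n_initial = n_initial,
         removed_ids = removed_ids),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("<cascade_report> %d initial knees\n", x$n_initial))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Select vKR case knees
#'
#' From the cascade-eligible knees (with surgically replaced knees removed by
#' the evaluability rule), keeps knees that (a) reach vKR case status for the
#' first time at exactly `target_month`, (b) score strictly below the
#' high-risk threshold at the defining visit t0 = `target_month` - 12, and
#' (c) have readable cartilage data at every annual visit from month 0
#' through `require_mri_through`.
#'
#' @param cohort A [vkr_cohort()].
#' @param eligible Knee ids surviving [apply_exclusion_cascade()].
#' @param params [vkr_params()].
#' @param target_month Attributed case month (default 60).
#' @param require_mri_through Last month of the required MRI run (default 48).
#' @return Character vector of case knee ids.
#' @export
select_cases <- function(cohort, eligible, params = vkr_params(),
                         target_month = 60L, require_mri_through = 48L) {
  stopifnot(inherits(cohort, "vkr_cohort"))
  k <- cohort$knees[cohort$knees$knee_id %in% eligible, , drop = FALSE]
  # surgical replacements by the attributed month are counted as surgical,
  # never as virtual, cases
  k <- k[is.na(k$surgical_kr_month) | k$surgical_kr_month > target_month, , drop = FALSE]
  sub <- vkr_cohort(k, cohort$visits[cohort$visits$knee_id %in% k$knee_id, , drop = FALSE])
  fcm <- first_case_months(sub, params)
  ids <- names(fcm)[!is.na(fcm) & fcm == target_month]
  if (length(ids) == 0L) return(character())
  # composite score at the defining visit must sit in the high-risk tail
  a <- assess_cohort(sub, params, t0_months = target_month - 12L)
  a <- a[match(ids, a$knee_id), , drop = FALSE]
  ids <- ids[!is.na(a$composite_score) & a$composite_score < params$threshold]
  # complete annual MRI run from baseline through require_mri_through
  need <- vkr_visit_months()[vkr_visit_months() <= require_mri_through]
  v <- cohort$visits[cohort$visits$knee_id %in% ids &
                       cohort$visits$visit_month %in% need, , drop = FALSE]
  ok_tab <- tapply(v$cart_readable, v$knee_id,
                   function(z) isTRUE(sum(z, na.rm = TRUE) == length(need)))
  ids <- ids[ids %in% names(ok_tab)[unlist(ok_tab)]]
  sort(ids)
}

#' Select vKR control knees
#'
#' Controls are eligible knees whose composite score at the defining visit
#' t0 = `target_month` - 12 lies at or above the empirical
#' (1 - `control_bottom_fraction`) quantile of the eligible scored
#' population -- the lowest-risk stratum -- excluding case knees, knees with
#' a surgical replacement by `target_month`, and knees whose contralateral
#' knee is a vKR case or was surgically replaced by `target_month`.
#'
#' @param cohort A [vkr_cohort()].
#' @param eligible Knee ids surviving the cascade.
#' @param cases Case knee ids (from [select_cases()]).
#' @param params [vkr_params()].
#' @param target_month Attributed case month (default 60).
#' @return Character vector of control knee ids.
#' @export
select_controls <- function(cohort, eligible, cases, params = vkr_params(),
                            target_month = 60L) {
  stopifnot(inherits(cohort, "vkr_cohort"))
  k <- cohort$knees[cohort$knees$knee_id %in% eligible, , drop = FALSE]
  sub <- vkr_cohort(k, cohort$visits[cohort$visits$knee_id %in% k$knee_id, , drop = FALSE])
  a <- assess_cohort(sub, params, t0_months = target_month - 12L)
  scored <- a[!is.na(a$composite_score), , drop = FALSE]
  if (nrow(scored) == 0L) return(character())
  s <- sort(scored$composite_score)
  n <- length(s)
  n_sel <- floor(n * params$control_bottom_fraction)
  if (n_sel == 0L) return(character())
  cutoff <- s[n - n_sel + 1L]
  low_risk <- scored$knee_id[scored$composite_score >= cutoff]

  kr_by_target <- !is.na(k$surgical_kr_month) & k$surgical_kr_month <= target_month
  contra <- contralateral_ids(k)
  contra_case_or_kr <- (!is.na(contra) & contra %in% cases) |
    (!is.na(contra) & contra %in% k$knee_id[kr_by_target])
  bad <- k$knee_id[kr_by_target | contra_case_or_kr]
  sort(setdiff(setdiff(low_risk, cases), bad))
}

# per-knee frame of the matching variables
matching_frame <- function(cohort, ids) {
  k <- cohort$knees[match(ids, cohort$knees$knee_id), , drop = FALSE]
  data.frame(
    knee_id = k$knee_id, participant_id = k$participant_id, sex = k$sex,
    age = k$age_baseline, klg_stratum = k$klg_stratum,
    jsn_dominant = k$jsn_dominant, stringsAsFactors = FALSE
  )
}

#' 1:1 stratified case-control matching
#'
#' Greedy matching without replacement: cases are processed in ascending
#' knee-id order; within exact strata of sex, Kellgren-Lawrence stratum
#' (0-1, 2, 3, 4) and dominant joint-space-narrowing compartment, the unused
#' control with the smallest absolute baseline-age difference within the
#' caliper is taken, ties broken by a seeded uniform draw. Cases with no
#' admissible control are reported unmatched.
#'
#' @param cases,controls Data frames with columns `knee_id`,
#'   `participant_id`, `sex`, `age`, `klg_stratum`, `jsn_dominant` (see
#'   [match_pairs_cohort()] for the cohort-level wrapper).
#' @param age_caliper Maximum |age difference| in years (default 5).
#' @param seed Integer seed for tie-breaking.
#' @return List with `pairs` (one row per matched pair incl. `age_gap`) and
#'   `unmatched` (case knee ids).
#' @export
match_pairs <- function(cases, controls, age_caliper = 5, seed = 1L) {
  if (age_caliper <= 0) stop("age_caliper must be positive")
  req <- c("knee_id", "participant_id", "sex", "age", "klg_stratum", "jsn_dominant")
  stopifnot(all(req %in% names(cases)), all(req %in% names(controls)))
  if (any(cases$knee_id %in% controls$knee_id)) {
    stop("case and control pools must be disjoint")
  }
  cases <- cases[order(cases$knee_id), , drop = FALSE]
  used <- rep(FALSE, nrow(controls))
  set.seed(substream_seed(seed, 7559L))
  rows <- vector("list", nrow(cases))
  unmatched <- character()
  for (i in seq_len(nrow(cases))) {
    ca <- cases[i, ]
    cand <- which(
      !used &
        controls$sex == ca$sex &
        controls$klg_stratum == ca$klg_stratum &
        controls$jsn_dominant == ca$jsn_dominant &
        abs(controls$age - ca$age) <= age_caliper
    )
    if (length(cand) == 0L) {
      unmatched <- c(unmatched, ca$knee_id)
      next
    }
    gap <- abs(controls$age[cand] - ca$age)
    best <- cand[gap == min(gap)]
    pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    used[pick] <- TRUE
    rows[[i]] <- data.frame(
      case_knee_id = ca$knee_id, control_knee_id = controls$knee_id[pick],
      case_participant_id = ca$participant_id,
      control_participant_id = controls$participant_id[pick],
      sex = ca$sex, case_age = ca$age, control_age = controls$age[pick],
      klg_stratum = ca$klg_stratum, jsn_dominant = ca$jsn_dominant,
      age_gap = abs(controls$age[pick] - ca$age),
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(
      case_knee_id = character(), control_knee_id = character(),
      case_participant_id = character(), control_participant_id = character(),
      sex = character(), case_age = numeric(), control_age = numeric(),
      klg_stratum = character(), jsn_dominant = character(),
      age_gap = numeric(), stringsAsFactors = FALSE
    )
  } else {
    rownames(pairs) <- NULL
    stopifnot(
      !anyDuplicated(pairs$control_knee_id),
      all(pairs$age_gap <= age_caliper)
    )
  }
  list(pairs = pairs, unmatched = unmatched)
}

#' Match cases to controls within a cohort
#'
#' Convenience wrapper assembling the matching variables from the cohort and
#' calling [match_pairs()].
#'
#' @param cohort A [vkr_cohort()].
#' @param case_ids,control_ids Knee id vectors.
#' @param age_caliper,seed Passed to [match_pairs()].
#' @return As [match_pairs()].
#' @export
match_pairs_cohort <- function(cohort, case_ids, control_ids,
                               age_caliper = 5, seed = 1L) {
  match_pairs(matching_frame(cohort, case_ids),
              matching_frame(cohort, control_ids),
              age_caliper = age_caliper, seed = seed)
}
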