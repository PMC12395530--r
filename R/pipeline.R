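#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"csv"` (read one from
#'   `input_dir` written by [write_cohort_csv()]).
#' @param sim A [sim_config()] (synthetic mode).
#' @param params A [vkr_params()].
#' @param target_month Attributed case month (default 60).
#' @param intervals List of `c(from, to)` month pairs; the first is the
#'   primary two-year interval, months 24 to 48, followed by the four annual
#'   intervals.
#' @param regions Region names for the comparison tables.
#' @param age_caliper Matching age caliper in years.
#' @param seed Seed for matching tie-breaks.
#' @param input_dir Cohort directory (csv mode).
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       sim = sim_config(),
                       params = vkr_params(),
                       target_month = 60L,
                       intervals = list(c(24L, 48L), c(36L, 48L), c(24L, 36L),
                                        c(12L, 24L), c(0L, 12L)),
                       regions = c("cMFTC", "MFTC", "cLFTC", "LFTC", "cMT", "ccMF"),
                       age_caliper = 5,
                       seed = 1L,
                       input_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "csv" && (is.null(input_dir) || !dir.exists(input_dir))) {
    stop("csv mode needs an existing input_dir")
  }
  structure(
    list(mode = mode, sim = sim, params = params,
         target_month = as.integer(target_month), intervals = intervals,
         regions = regions, age_caliper = age_caliper, seed = as.integer(seed),
         input_dir = input_dir),
    class = "run_config"
  )
}

#' Run the full vKR analysis pipeline
#'
#' Composes the stages end-to-end: obtain a cohort (synthetic or CSV), apply
#' the exclusion cascade, assess every knee-year with the vKR rule, select
#' month-`target_month` first-time cases and low-risk controls, match 1:1
#' within strata, compute interval cartilage changes, and produce the
#' matched-pair comparison and maintenance-split tables. All intermediate
#' tables are written as CSV to `out_dir`, together with an exclusion log
#' (one machine-readable reason per excluded knee) and a JSON manifest.
#' Identical configurations give identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `cascade`, `assessments`, `cases`, `controls`, `matching`, `results`,
#'   `maintenance`, `out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (config$mode == "synthetic") {
    inject_missingness(generate_cohort(config$sim), config$sim)
  } else {
    read_cohort_csv(config$input_dir)
  }

  cascade <- apply_exclusion_cascade(cohort, config$target_month)
  assessments <- if (nrow(cohort$knees) > 0L) {
    sub <- vkr_cohort(
      cohort$knees[cohort$knees$knee_id %in% cascade$eligible, , drop = FALSE],
      cohort$visits[cohort$visits$knee_id %in% cascade$eligible, , drop = FALSE]
    )
    assess_cohort(sub, config$params)
  } else {
    assess_cohort(cohort, config$params)
  }
  cases <- select_cases(cohort, cascade$eligible, config$params,
                        target_month = config$target_month)
  controls <- select_controls(cohort, cascade$eligible, cases, config$params,
                              target_month = config$target_month)
  matching <- match_pairs_cohort(cohort, cases, controls,
                                 age_caliper = config$age_caliper,
                                 seed = config$seed)
  results <- build_table(cohort, matching$pairs, regions = config$regions,
                         intervals = config$intervals)
  maintenance <- if (length(cases) > 0L) {
    maintenance_comparison(cohort, cases, regions = config$regions,
                           interval = config$intervals[[1L]],
                           params = config$params)
  } else {
    list(table = NULL, dropped = character(), status = character())
  }

  changes <- pipeline_changes(cohort, matching$pairs, config)
  exclusions <- pipeline_exclusion_log(cascade, cohort, cases, controls, matching)

  utils::write.csv(cascade$steps, file.path(out_dir, "cascade.csv"), row.names = FALSE)
  utils::write.csv(assessments, file.path(out_dir, "assessments.csv"), row.names = FALSE)
  utils::write.csv(matching$pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  utils::write.csv(changes, file.path(out_dir, "changes.csv"), row.names = FALSE, na = "")
  utils::write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE, na = "")
  if (!is.null(maintenance$table)) {
    utils::write.csv(maintenance$table, file.path(out_dir, "maintenance.csv"),
                     row.names = FALSE, na = "")
  }
  utils::write.csv(exclusions, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  manifest <- list(
    mode = config$mode, seed = config$seed, target_month = config$target_month,
    n_knees = nrow(cohort$knees), n_eligible = length(cascade$eligible),
    n_cases = length(cases), n_controls = length(controls),
    n_pairs = nrow(matching$pairs), n_unmatched = length(matching$unmatched),
    sim = if (config$mode == "synthetic") unclass(config$sim) else NULL,
    params = unclass(config$params),
    package_version = as.character(utils::packageVersion("vkr"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (nrow(matching$pairs) == 0L) {
    warning("no matched case-control pairs; results table is empty")
  }
  invisible(list(
    cohort = cohort, cascade = cascade, assessments = assessments,
    cases = cases, controls = controls, matching = matching,
    results = results, maintenance = maintenance, changes = changes,
    out_dir = out_dir
  ))
}

pipeline_changes <- function(cohort, pairs, config) {
  empty <- data.frame(
    knee_id = character(), role = character(), region = character(),
    from_month = integer(), to_month = integer(), delta_um = numeric(),
    stringsAsFactors = FALSE
  )
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  ids <- c(pairs$case_knee_id, pairs$control_knee_id)
  roles <- rep(c("case", "control"), each = nrow(pairs))
  rows <- list()
  for (iv in config$intervals) {
    for (rg in config$regions) {
      rows[[length(rows) + 1L]] <- data.frame(
        knee_id = ids, role = roles, region = rg,
        from_month = iv[1L], to_month = iv[2L],
        delta_um = interval_changes(cohort, ids, rg, iv[1L], iv[2L]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pipeline_exclusion_log <- function(cascade, cohort, cases, controls, matching) {
  rows <- list()
  for (step in names(cascade$removed_ids)) {
    ids <- cascade$removed_ids[[step]]
    if (length(ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        knee_id = ids, stage = "cascade",
        reason = gsub(" ", "_", step), stringsAsFactors = FALSE
      )
    }
  }
  if (length(matching$unmatched)) {
    rows[[length(rows) + 1L]] <- data.frame(
      knee_id = matching$unmatched, stage = "matching",
      reason = "no_control_in_stratum_within_caliper", stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(knee_id = character(), stage = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
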