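#' Region thickness at one visit
#'
#' Aggregates subregion mean thickness into a region value, in micrometres.
#' Plate values (MT, LT, cMF, cLF) are weighted means of their member
#' subregions (equal weights unless the region spec carries weights);
#' femorotibial aggregates (cMFTC, MFTC and lateral analogues) are the sum
#' of the tibial and femoral plate values, so cMFTC = cMT + ccMF.
#'
#' @param visit One visit row (a one-row data frame or list carrying the
#'   `th_*` thickness columns and `cart_readable`).
#' @param region A `region_spec` or standard region name (see
#'   [ftc_regions()]).
#' @return Thickness in micrometres.
#' @export
#' @examples
#' v <- c(as.list(setNames(rep(1500, 16), paste0("th_", subregion_labels()))),
#'        list(cart_readable = TRUE))
#' region_thickness(v, "cMFTC")  # 3000
region_thickness <- function(visit, region) {
  region <- resolve_region(region)
  if (!isTRUE(visit[["cart_readable"]])) {
    stop("visit is not readable; region thickness undefined")
  }
  take <- function(members, weights) {
    if (length(members) == 0L) return(0)
    vals <- vapply(paste0("th_", members), function(cl) {
      x <- visit[[cl]]
      if (is.null(x) || is.na(x)) {
        stop("missing subregion thickness: ", sub("^th_", "", cl))
      }
      as.numeric(x)
    }, numeric(1))
    sum(vals * weights)
  }
  take(region$tibial, region$tibial_weights) +
    take(region$femoral, region$femoral_weights)
}

# vectorised region thickness over visit rows; NA where unreadable/incomplete
region_values <- function(visits, region) {
  region <- resolve_region(region)
  out <- rep(NA_real_, nrow(visits))
  if (nrow(visits) == 0L) return(out)
  plate <- function(members, weights) {
    if (length(members) == 0L) return(rep(0, nrow(visits)))
    m <- as.matrix(visits[, paste0("th_", members), drop = FALSE])
    as.numeric(m %*% weights)
  }
  val <- plate(region$tibial, region$tibial_weights) +
    plate(region$femoral, region$femoral_weights)
  ok <- visits$cart_readable & !is.na(val)
  out[ok] <- val[ok]
  out
}

#' Interval change in region thickness
#'
#' Change in a region's cartilage thickness between two annual visits, in
#' micrometres, with loss negative. The change is defined only when both
#' visits are present and readable; otherwise `delta` is NA and `complete`
#' is FALSE (the knee is dropped pairwise from analyses of that variable).
#'
#' @param knee A [knee_series()].
#' @param region Region spec or name.
#' @param from_month,to_month Visit months with `to_month > from_month`.
#' @return One-row data frame: `knee_id`, `region`, `from_month`,
#'   `to_month`, `delta`, `complete`.
#' @export
interval_change <- function(knee, region, from_month, to_month) {
  stopifnot(inherits(knee, "knee_series"))
  if (to_month <= from_month) stop("to_month must exceed from_month")
  region <- resolve_region(region)
  v <- knee$visits
  val_at <- function(m) {
    r <- v[v$visit_month == m, , drop = FALSE]
    if (nrow(r) != 1L || !isTRUE(r$cart_readable)) return(NA_real_)
    region_values(r, region)
  }
  a <- val_at(from_month)
  b <- val_at(to_month)
  delta <- b - a
  data.frame(
    knee_id = knee$info$knee_id, region = region$name,
    from_month = from_month, to_month = to_month,
    delta = delta, complete = !is.na(delta), stringsAsFactors = FALSE
  )
}

# vectorised interval changes for many knees at once
interval_changes <- function(cohort, knee_ids, region, from_month, to_month) {
  region <- resolve_region(region)
  v <- cohort$visits
  pick <- function(m) {
    r <- v[v$visit_month == m, , drop = FALSE]
    vals <- region_values(r, region)
    vals[match(knee_ids, r$knee_id)]
  }
  pick(to_month) - pick(from_month)
}

#' Location-independent thinning and thickening scores
#'
#' Over all 16 subregion changes between two visits, the thinning score is
#' the sum of the negative changes (<= 0) and the thickening score the sum
#' of the positive changes (>= 0); their sum equals the total summed
#' subregion change. Changes of magnitude at most `sdc` (a smallest
#' detectable change hook, default 0) are treated as no change.
#'
#' @param knee A [knee_series()].
#' @param from_month,to_month Visit months.
#' @param sdc Smallest-detectable-change threshold in micrometres.
#' @return One-row data frame: `knee_id`, `from_month`, `to_month`,
#'   `thinning`, `thickening`, `complete`.
#' @export
thinning_thickening_scores <- function(knee, from_month, to_month, sdc = 0) {
  stopifnot(inherits(knee, "knee_series"))
  if (to_month <= from_month) stop("to_month must exceed from_month")
  v <- knee$visits
  row_at <- function(m) {
    r <- v[v$visit_month == m, , drop = FALSE]
    if (nrow(r) != 1L || !isTRUE(r$cart_readable)) return(NULL)
    as.numeric(r[1L, thickness_columns()])
  }
  a <- row_at(from_month)
  b <- row_at(to_month)
  if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) {
    return(data.frame(
      knee_id = knee$info$knee_id, from_month = from_month,
      to_month = to_month, thinning = NA_real_, thickening = NA_real_,
      complete = FALSE, stringsAsFactors = FALSE
    ))
  }
  d <- b - a
  d[abs(d) <= sdc] <- 0
  data.frame(
    knee_id = knee$info$knee_id, from_month = from_month, to_month = to_month,
    thinning = sum(pmin(d, 0)), thickening = sum(pmax(d, 0)),
    complete = TRUE, stringsAsFactors = FALSE
  )
}

# vectorised thinning/thickening for many knees; list of two numeric vectors
thinning_thickening_many <- function(cohort, knee_ids, from_month, to_month,
                                     sdc = 0) {
  v <- cohort$visits
  mat_at <- function(m) {
    r <- v[v$visit_month == m, , drop = FALSE]
    m16 <- as.matrix(r[, thickness_columns(), drop = FALSE])
    m16[!r$cart_readable, ] <- NA_real_
    m16[match(knee_ids, r$knee_id), , drop = FALSE]
  }
  d <- mat_at(to_month) - mat_at(from_month)
  d[!is.na(d) & abs(d) <= sdc] <- 0
  list(
    thinning = apply(d, 1L, function(z) if (anyNA(z)) NA_real_ else sum(pmin(z, 0))),
    thickening = apply(d, 1L, function(z) if (anyNA(z)) NA_real_ else sum(pmax(z, 0)))
  )
}

#' Change in minimal medial joint-space width
#'
#' Radiographic mJSW change between two visits, converted from millimetres
#' to micrometres; loss is negative. Undefined (NA) when either visit lacks
#' an mJSW measurement, in which case the pair is dropped from the mJSW
#' sub-analysis.
#'
#' @param knee A [knee_series()].
#' @param from_month,to_month Visit months.
#' @return Change in micrometres, or NA.
#' @export
mjsw_change <- function(knee, from_month, to_month) {
  stopifnot(inherits(knee, "knee_series"))
  if (to_month <= from_month) stop("to_month must exceed from_month")
  v <- knee$visits
  get <- function(m) {
    r <- v[v$visit_month == m, , drop = FALSE]
    if (nrow(r) != 1L) return(NA_real_)
    r$mjsw_medial
  }
  (get(to_month) - get(from_month)) * 1000
}
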