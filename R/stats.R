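#' Paired t-test on matched case-control values
#'
#' Two-sided paired t-test on case minus control differences (NA pairs are
#' dropped first, i.e. pairwise-complete analysis).
#'
#' @param case_values,control_values Equal-length numeric vectors.
#' @return List with `t`, `p`, `df`, `n`, `mean_diff`.
#' @export
paired_t <- function(case_values, control_values) {
  if (length(case_values) != length(control_values)) {
    stop("case and control vectors must have equal length")
  }
  ok <- !is.na(case_values) & !is.na(control_values)
  d <- case_values[ok] - control_values[ok]
  n <- length(d)
  if (n < 2L) stop("paired t-test needs at least 2 complete pairs")
  if (stats::sd(d) == 0) stop("all differences identical; paired t-test degenerate")
  tt <- stats::t.test(case_values[ok], control_values[ok], paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = n, mean_diff = mean(d))
}

# conditional log-likelihood of the 1:1 matched design on difference rows D
clogit_loglik <- function(beta, D) {
  eta <- as.numeric(D %*% beta)
  sum(-log1p(exp(-eta)))
}

#' 1:1 conditional logistic regression
#'
#' Fits the conditional likelihood of a 1:1 matched case-control design,
#' prod_j exp(b'x_case_j) / (exp(b'x_case_j) + exp(b'x_control_j)),
#' equivalently an intercept-free logistic model on within-pair covariate
#' differences with all outcomes equal to 1, by Newton-Raphson iterated to a
#' gradient norm below 1e-10. The exposure is divided by `scale_sd` (by
#' convention the control-group SD of the same variable) before fitting, so
#' `exp(beta[1])` is the odds ratio per control-SD.
#'
#' Two covariance estimates are returned: the model-based inverse observed
#' information, and a cluster-robust sandwich A^-1 B A^-1 in which B sums
#' the pair-level score contributions over clusters of pairs connected
#' through a shared participant, accommodating participants who contribute
#' two case knees or two control knees to different pairs (with all
#' participants distinct it reduces to the ordinary independent-pairs
#' sandwich). Complete separation (a direction in which the
#' likelihood increases without bound) is reported as an error rather than
#' silently producing a divergent estimate.
#'
#' @param x_case,x_control Exposure values per pair.
#' @param scale_sd Positive scale (control-group SD) for the exposure.
#' @param covariate_diffs Optional matrix of additional within-pair
#'   covariate differences (case minus control), e.g. BMI-category
#'   indicators from [bmi_adjustment_covariates()]; not rescaled.
#' @param case_cluster,control_cluster Optional participant ids per pair for
#'   the sandwich clustering; default gives every knee its own cluster.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return Object of class `vkr_clogit`: `beta`, `se_model`, `se_robust`,
#'   `or_per_sd`, `ci_low`, `ci_high` (robust, on the exposure), `p_value`,
#'   `n_pairs`, `loglik`, `converged`.
#' @export
clogit_1to1 <- function(x_case, x_control, scale_sd,
                        covariate_diffs = NULL,
                        case_cluster = NULL, control_cluster = NULL,
                        conf_level = 0.95) {
  if (length(x_case) != length(x_control)) {
    stop("x_case and x_control must have equal length")
  }
  if (!is.numeric(scale_sd) || length(scale_sd) != 1L || is.na(scale_sd) ||
      scale_sd <= 0) {
    stop("scale_sd must be a positive number")
  }
  ok <- !is.na(x_case) & !is.na(x_control)
  if (!is.null(covariate_diffs)) {
    covariate_diffs <- as.matrix(covariate_diffs)
    ok <- ok & !apply(covariate_diffs, 1L, anyNA)
  }
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 complete pairs")
  d1 <- (x_case[ok] - x_control[ok]) / scale_sd
  D <- cbind(exposure = d1)
  if (!is.null(covariate_diffs)) D <- cbind(D, covariate_diffs[ok, , drop = FALSE])
  p <- ncol(D)

  # separation: the univariate conditional likelihood is monotone when all
  # differences share one sign
  if (p == 1L && ((all(d1 >= 0) && any(d1 > 0)) || (all(d1 <= 0) && any(d1 < 0)))) {
    stop("complete separation: all within-pair differences share one sign; ",
         "conditional likelihood is unbounded")
  }

  beta <- rep(0, p)
  converged <- FALSE
  ll <- clogit_loglik(beta, D)
  for (iter in 1:100) {
    eta <- as.numeric(D %*% beta)
    sig <- stats::plogis(eta)           # P(case ranks first in its pair)
    grad <- colSums((1 - sig) * D)
    W <- sig * (1 - sig)
    A <- crossprod(D, W * D)            # observed information
    if (any(!is.finite(A)) || rcond_safe(A) < 1e-10) {
      stop("information matrix is singular; likely separation or collinearity")
    }
    step <- solve(A, grad)
    new_beta <- beta + step
    new_ll <- clogit_loglik(new_beta, D)
    # halve only on a resolvable decrease: near the optimum the remaining
    # improvement is below double precision and the full step must stand
    halvings <- 0L
    while (new_ll < ll - 1e-10 * (abs(ll) + 1) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- clogit_loglik(new_beta, D)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    ll <- new_ll
    if (max(abs(beta)) > 50) {
      stop("estimates diverging; likely complete separation")
    }
    eta <- as.numeric(D %*% beta)
    sig <- stats::plogis(eta)
    grad <- colSums((1 - sig) * D)
    if (sqrt(sum(grad^2)) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  if (!converged) stop("Newton iteration failed to converge")

  W <- sig * (1 - sig)
  A <- crossprod(D, W * D)
  V_model <- solve(A)

  # pair-level score contributions (1 - sigma) D_j, summed over clusters of
  # pairs connected through a shared participant; with all participants
  # distinct this is the ordinary independent-pairs sandwich
  U <- (1 - sig) * D
  cl_case <- if (is.null(case_cluster)) paste0("case", seq_len(n)) else as.character(case_cluster[ok])
  cl_ctrl <- if (is.null(control_cluster)) paste0("ctrl", seq_len(n)) else as.character(control_cluster[ok])
  comp <- pair_components(cl_case, cl_ctrl)
  G <- rowsum(U, group = comp)
  B <- crossprod(G)
  V_robust <- V_model %*% B %*% V_model
  V_robust <- (V_robust + t(V_robust)) / 2

  if (any(diag(V_model) <= 0) || any(diag(V_robust) <= 0)) {
    stop("covariance estimate is not positive; the design matrix is too ",
         "ill-conditioned for a stable fit")
  }
  se_model <- sqrt(diag(V_model))
  se_robust <- sqrt(diag(V_robust))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      beta = beta, se_model = se_model, se_robust = se_robust,
      or_per_sd = unname(exp(beta[1L])),
      ci_low = unname(exp(beta[1L] - z * se_robust[1L])),
      ci_high = unname(exp(beta[1L] + z * se_robust[1L])),
      p_value = unname(2 * stats::pnorm(-abs(beta[1L] / se_robust[1L]))),
      p_value_model = unname(2 * stats::pnorm(-abs(beta[1L] / se_model[1L]))),
      n_pairs = n, loglik = ll, converged = converged
    ),
    class = "vkr_clogit"
  )
}

# connected components of pairs linked by a shared participant (union-find)
pair_components <- function(cl_case, cl_ctrl) {
  labels <- unique(c(cl_case, cl_ctrl))
  parent <- seq_along(labels)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- match(cl_case, labels)
  b <- match(cl_ctrl, labels)
  for (j in seq_along(a)) {
    ra <- find(a[j])
    rb <- find(b[j])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(a, find, integer(1))
}

rcond_safe <- function(A) {
  out <- tryCatch(rcond(A), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}

#' @export
print.vkr_clogit <- function(x, ...) {
  cat(sprintf(
    "<vkr_clogit> n = %d pairs; OR per control-SD = %.3f (95%% CI %.3f-%.3f), robust p = %.4g\n",
    x$n_pairs, x$or_per_sd, x$ci_low, x$ci_high, x$p_value
  ))
  invisible(x)
}

#' BMI-category adjustment covariates
#'
#' Maps BMI to the standard WHO categories -- normal (< 25), overweight
#' ([25, 30)), obese (>= 30), half-open at the boundaries -- and returns the
#' within-pair differences of the overweight and obese indicators (normal is
#' the reference).
#'
#' @param case_bmi,control_bmi BMI (kg/m^2) at the start of the observation
#'   interval, per pair.
#' @return Matrix with columns `d_overweight`, `d_obese`.
#' @export
#' @examples
#' bmi_adjustment_covariates(31, 26)  # obese vs overweight: (-1, +1)
bmi_adjustment_covariates <- function(case_bmi, control_bmi) {
  if (any(c(case_bmi, control_bmi) <= 0, na.rm = TRUE)) {
    stop("BMI must be positive")
  }
  cat3 <- function(b) cbind(overweight = as.numeric(b >= 25 & b < 30),
                            obese = as.numeric(b >= 30))
  d <- cat3(case_bmi) - cat3(control_bmi)
  colnames(d) <- c("d_overweight", "d_obese")
  d
}

#' Kruskal-Wallis comparison of two groups
#'
#' Mid-rank Kruskal-Wallis H statistic with tie correction and a chi-squared
#' p-value on 1 degree of freedom. When every value in both groups is
#' identical the statistic is 0 with p = 1 (complete exchangeability) rather
#' than an error.
#'
#' @param group_a,group_b Numeric vectors (NAs dropped).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (length(group_a) + length(group_b) < 3L) stop("combined n must be >= 3")
  vals <- c(group_a, group_b)
  if (length(unique(vals)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(list(group_a, group_b))
  list(H = unname(kt$statistic), p = kt$p.value)
}

# BMI at the start of an interval, falling back to the closest earlier visit
bmi_at_month <- function(cohort, knee_ids, month) {
  v <- cohort$visits[cohort$visits$visit_month <= month & cohort$visits$pro_present &
                       !is.na(cohort$visits$bmi), , drop = FALSE]
  v <- v[order(v$knee_id, v$visit_month), , drop = FALSE]
  last <- tapply(v$bmi, v$knee_id, function(z) z[length(z)])
  as.numeric(last[knee_ids])
}

#' Matched-pair comparison table
#'
#' Builds the case-versus-control comparison table for a set of regions and
#' observation intervals: per row, pairwise-complete group means/SDs of the
#' interval thickness change, the paired t-test, and the 1:1 conditional
#' logistic odds ratio per control-SD of cartilage *loss* (so OR > 1 means
#' greater loss in cases), with cluster-robust confidence intervals, both
#' unadjusted and adjusted for BMI category at the interval start. The
#' location-independent thinning/thickening scores are appended for the
#' primary interval when `include_scores` is TRUE.
#'
#' @param cohort A [vkr_cohort()].
#' @param pairs Matched-pair data frame from [match_pairs()].
#' @param regions Character vector of region names.
#' @param intervals List of `c(from_month, to_month)` pairs.
#' @param include_scores Append thinning/thickening score rows for the first
#'   interval.
#' @return Data frame, one row per (variable, interval).
#' @export
build_table <- function(cohort, pairs,
                        regions = c("cMFTC", "MFTC", "cLFTC", "LFTC", "cMT", "ccMF"),
                        intervals = list(c(24L, 48L)),
                        include_scores = TRUE) {
  stopifnot(inherits(cohort, "vkr_cohort"))
  empty <- data.frame(
    variable = character(), from_month = integer(), to_month = integer(),
    n_pairs = integer(), case_mean = numeric(), case_sd = numeric(),
    control_mean = numeric(), control_sd = numeric(), t_stat = numeric(),
    t_pvalue = numeric(), beta = numeric(), or_per_sd = numeric(),
    ci_low = numeric(), ci_high = numeric(), p_unadjusted = numeric(),
    or_adjusted = numeric(), ci_adj_low = numeric(), ci_adj_high = numeric(),
    p_adjusted = numeric(), stringsAsFactors = FALSE
  )
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  rows <- list()
  for (iv in intervals) {
    from <- iv[1L]
    to <- iv[2L]
    vars <- lapply(regions, function(rg) {
      list(name = rg,
           case = interval_changes(cohort, pairs$case_knee_id, rg, from, to),
           ctrl = interval_changes(cohort, pairs$control_knee_id, rg, from, to))
    })
    if (include_scores && identical(iv, intervals[[1L]])) {
      tc <- thinning_thickening_many(cohort, pairs$case_knee_id, from, to)
      tk <- thinning_thickening_many(cohort, pairs$control_knee_id, from, to)
      vars <- c(vars, list(
        list(name = "ThinningScore", case = tc$thinning, ctrl = tk$thinning),
        list(name = "ThickeningScore", case = tc$thickening, ctrl = tk$thickening)
      ))
    }
    for (vr in vars) {
      rows[[length(rows) + 1L]] <- comparison_row(
        cohort, pairs, vr$name, from, to, vr$case, vr$ctrl
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

comparison_row <- function(cohort, pairs, variable, from, to, case_vals, ctrl_vals) {
  ok <- !is.na(case_vals) & !is.na(ctrl_vals)
  n <- sum(ok)
  base <- data.frame(
    variable = variable, from_month = from, to_month = to, n_pairs = n,
    case_mean = NA_real_, case_sd = NA_real_, control_mean = NA_real_,
    control_sd = NA_real_, t_stat = NA_real_, t_pvalue = NA_real_,
    beta = NA_real_, or_per_sd = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, p_unadjusted = NA_real_, or_adjusted = NA_real_,
    ci_adj_low = NA_real_, ci_adj_high = NA_real_, p_adjusted = NA_real_,
    stringsAsFactors = FALSE
  )
  if (n < 3L) return(base)
  cv <- case_vals[ok]
  kv <- ctrl_vals[ok]
  base$case_mean <- mean(cv)
  base$case_sd <- stats::sd(cv)
  base$control_mean <- mean(kv)
  base$control_sd <- stats::sd(kv)
  tt <- tryCatch(paired_t(cv, kv), error = function(e) NULL)
  if (!is.null(tt)) {
    base$t_stat <- tt$t
    base$t_pvalue <- tt$p
  }
  sd_ctrl <- stats::sd(kv)
  if (is.na(sd_ctrl) || sd_ctrl == 0) return(base)
  # exposure is loss (sign-flipped change): OR > 1 <=> greater loss in cases
  fit <- tryCatch(
    clogit_1to1(-cv, -kv, scale_sd = sd_ctrl,
                case_cluster = pairs$case_participant_id[ok],
                control_cluster = pairs$control_participant_id[ok]),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    base$beta <- fit$beta[1L]
    base$or_per_sd <- fit$or_per_sd
    base$ci_low <- fit$ci_low
    base$ci_high <- fit$ci_high
    base$p_unadjusted <- fit$p_value
  }
  bmi_case <- bmi_at_month(cohort, pairs$case_knee_id[ok], from)
  bmi_ctrl <- bmi_at_month(cohort, pairs$control_knee_id[ok], from)
  adj <- tryCatch(
    clogit_1to1(-cv, -kv, scale_sd = sd_ctrl,
                covariate_diffs = bmi_adjustment_covariates(bmi_case, bmi_ctrl),
                case_cluster = pairs$case_participant_id[ok],
                control_cluster = pairs$control_participant_id[ok]),
    error = function(e) NULL
  )
  if (!is.null(adj)) {
    base$or_adjusted <- adj$or_per_sd
    base$ci_adj_low <- adj$ci_low
    base$ci_adj_high <- adj$ci_high
    base$p_adjusted <- adj$p_value
  }
  base
}

#' Maintenance-split sensitivity comparison
#'
#' Splits the month-60 case knees into those that sustained their pain/QOL
#' level at month 72 (vKR+/+) and those that did not (vKR+/-), and compares
#' the interval cartilage change between the two groups per region with the
#' Kruskal-Wallis test. Case knees without the month-72 PRO visit are
#' dropped and reported.
#'
#' @param cohort A [vkr_cohort()].
#' @param case_ids Month-60 first-time case knee ids.
#' @param regions Character vector of region names.
#' @param interval `c(from_month, to_month)` (default the two-year primary
#'   interval, months 24 to 48).
#' @param params [vkr_params()].
#' @return List with `table` (one row per region: group means/SDs, H, p) and
#'   `dropped` (knee ids without a month-72 assessment).
#' @export
maintenance_comparison <- function(cohort, case_ids,
                                   regions = c("cMFTC", "MFTC", "cLFTC",
                                               "LFTC", "cMT", "ccMF"),
                                   interval = c(24L, 48L),
                                   params = vkr_params()) {
  status <- character(0)
  kept <- character(0)
  dropped <- character(0)
  for (id in case_ids) {
    st <- tryCatch(maintenance_status(knee_series(cohort, id), params),
                   error = function(e) NA_character_)
    if (is.na(st)) {
      dropped <- c(dropped, id)
    } else {
      kept <- c(kept, id)
      status <- c(status, st)
    }
  }
  rows <- lapply(regions, function(rg) {
    ch <- interval_changes(cohort, kept, rg, interval[1L], interval[2L])
    a <- ch[status == "vKR+/+" & !is.na(ch)]
    b <- ch[status == "vKR+/-" & !is.na(ch)]
    kw <- tryCatch(kruskal_wallis(a, b), error = function(e) list(H = NA_real_, p = NA_real_))
    data.frame(
      variable = rg, n_maintained = length(a), n_not_maintained = length(b),
      maintained_mean = if (length(a)) mean(a) else NA_real_,
      maintained_sd = if (length(a) > 1L) stats::sd(a) else NA_real_,
      not_maintained_mean = if (length(b)) mean(b) else NA_real_,
      not_maintained_sd = if (length(b) > 1L) stats::sd(b) else NA_real_,
      H = kw$H, p = kw$p, stringsAsFactors = FALSE
    )
  })
  list(table = do.call(rbind, rows), dropped = dropped,
       status = stats::setNames(status, kept))
}
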