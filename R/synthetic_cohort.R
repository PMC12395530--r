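#' Simulation configuration
#'
#' Parameters of the synthetic OAI-like cohort generator. The cartilage-loss
#' defaults are two-year central medial femorotibial (cMFTC) change summaries
#' representative of case and control knees (-151 +/- 337 and -38 +/- 249
#' micrometres); the default Kellgren-Lawrence grade distribution (grades
#' 0..4: 0.26, 0.06, 0.26, 0.28, 0.14) is typical of a high-risk symptomatic
#' group.
#'
#' @param n_participants Number of participants; each contributes two knees.
#' @param seed Integer root seed. All randomness flows from it through a
#'   named substream per participant/knee, so enlarging the cohort does not
#'   perturb already-generated participants.
#' @param progressor_fraction Fraction of knees on the steeply worsening
#'   symptom trajectory (and, marginally, on the case-like structural
#'   trajectory).
#' @param case_loss_mean_2y,case_loss_sd_2y Mean/SD (micrometres) of the
#'   two-year cMFTC thickness change for structurally case-like knees.
#' @param control_loss_mean_2y,control_loss_sd_2y Same for control-like knees.
#' @param within_person_corr Correlation of the two knees' latent symptom
#'   scores within a participant.
#' @param symptom_structure_corr Correlation between a knee's latent symptom
#'   score and its latent structural-progression score.
#' @param missing_visit_prob Per-visit probability (never at month 0) that a
#'   PRO visit is missed / a cartilage image is unreadable, applied by
#'   [inject_missingness()].
#' @param klg_probs Probabilities of baseline Kellgren-Lawrence grades 0..4.
#' @param klg_missing_prob Probability that the central baseline KL reading
#'   is absent (an exclusion-cascade reason).
#' @param no_coverage_prob Probability of lacking continuous health coverage.
#' @param baseline_koos_missing_prob Probability that baseline KOOS scores
#'   were not recorded although the visit took place ("insufficient KOOS
#'   data" in the cascade).
#' @param maintain_prob Probability that a symptom progressor sustains (or
#'   worsens) its pain/QOL level from month 60 to month 72 rather than
#'   rebounding.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' cohort
sim_config <- function(n_participants = 1000L,
                       seed = 20260101L,
                       progressor_fraction = 0.10,
                       case_loss_mean_2y = -151,
                       case_loss_sd_2y = 337,
                       control_loss_mean_2y = -38,
                       control_loss_sd_2y = 249,
                       within_person_corr = 0.4,
                       symptom_structure_corr = 0.9,
                       missing_visit_prob = 0.05,
                       klg_probs = c(0.26, 0.06, 0.26, 0.28, 0.14),
                       klg_missing_prob = 0.02,
                       no_coverage_prob = 0.05,
                       baseline_koos_missing_prob = 0.005,
                       maintain_prob = 0.55) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    progressor_fraction = progressor_fraction,
    case_loss_mean_2y = case_loss_mean_2y, case_loss_sd_2y = case_loss_sd_2y,
    control_loss_mean_2y = control_loss_mean_2y,
    control_loss_sd_2y = control_loss_sd_2y,
    within_person_corr = within_person_corr,
    symptom_structure_corr = symptom_structure_corr,
    missing_visit_prob = missing_visit_prob,
    klg_probs = klg_probs, klg_missing_prob = klg_missing_prob,
    no_coverage_prob = no_coverage_prob,
    baseline_koos_missing_prob = baseline_koos_missing_prob,
    maintain_prob = maintain_prob
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(
    cfg$progressor_fraction, cfg$missing_visit_prob, cfg$klg_missing_prob,
    cfg$no_coverage_prob, cfg$baseline_koos_missing_prob, cfg$maintain_prob
  )
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_participants < 0L) stop("n_participants must be non-negative")
  if (length(cfg$klg_probs) != 5L || any(cfg$klg_probs < 0) ||
      abs(sum(cfg$klg_probs) - 1) > 1e-9) {
    stop("klg_probs must be 5 non-negative probabilities summing to 1")
  }
  if (cfg$case_loss_sd_2y <= 0 || cfg$control_loss_sd_2y <= 0) {
    stop("loss SDs must be positive")
  }
  if (cfg$within_person_corr < 0 || cfg$within_person_corr >= 1 ||
      cfg$symptom_structure_corr < 0 || cfg$symptom_structure_corr >= 1) {
    stop("correlations must lie in [0, 1)")
  }
  invisible(cfg)
}

# deterministic substream seed: small-int arithmetic kept exact in doubles
substream_seed <- function(seed, key) {
  m <- 2147483647
  as.integer((((seed %% m) * 48271) %% m + (key %% m) * 69621) %% m)
}

# stable numeric key for a knee id string (polynomial hash)
string_key <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% m
    h
  }, numeric(1))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# per-subregion annual change model: fraction of the cMFTC annual mean each
# subregion receives, and the SD scale relative to the central subregions.
# cMT and ccMF split the configured cMFTC change (their annual sums add up to
# the configured 2-year mean; their four independent annual increments add up
# to the configured 2-year SD). Peripheral and lateral subregions progress at
# fixed fractions of the central medial rate.
subregion_change_model <- function() {
  frac <- c(
    cMT = 0.47, eMT = 0.15, iMT = 0.15, aMT = 0.12, pMT = 0.12,
    cLT = 0.30, eLT = 0.10, iLT = 0.10, aLT = 0.08, pLT = 0.08,
    ccMF = 0.53, ecMF = 0.15, icMF = 0.15,
    ccLF = 0.30, ecLF = 0.10, icLF = 0.10
  )
  sd_scale <- c(
    cMT = 1, eMT = 0.6, iMT = 0.6, aMT = 0.6, pMT = 0.6,
    cLT = 0.8, eLT = 0.6, iLT = 0.6, aLT = 0.6, pLT = 0.6,
    ccMF = 1, ecMF = 0.6, icMF = 0.6,
    ccLF = 0.8, ecLF = 0.6, icLF = 0.6
  )
  list(frac = frac[subregion_labels()], sd_scale = sd_scale[subregion_labels()])
}

# plausible baseline mean thickness per subregion (micrometres)
subregion_baseline_means <- function() {
  mu <- c(
    cMT = 1700, eMT = 1500, iMT = 1600, aMT = 1500, pMT = 1400,
    cLT = 2000, eLT = 1600, iLT = 1700, aLT = 1700, pLT = 1500,
    ccMF = 1900, ecMF = 1500, icMF = 1600,
    ccLF = 2000, ecLF = 1600, icLF = 1700
  )
  mu[subregion_labels()]
}

#' Generate a synthetic longitudinal knee cohort
#'
#' Simulates participants with two knees each, observed at annual visits from
#' month 0 to month 72. A latent per-knee symptom score (correlated within
#' participants) drives KOOS pain and quality-of-life trajectories: all knees
#' decline slowly, and "progressor" knees (the top `progressor_fraction` of
#' the latent score) decline steeply between months 36 and 60, the window
#' that produces first-time vKR case status at the month-60 assessment. A
#' second latent structural score, correlated with the symptom score by
#' `symptom_structure_corr`, assigns each knee to the case-like or
#' control-like cartilage-loss distribution; annual subregion thickness
#' increments are Gaussian with the central medial subregions calibrated so
#' that the two-year cMFTC change matches the configured group mean/SD.
#' Surgical knee replacements occur with a probability that is logistic in
#' the latent symptom score, truncating the knee's subsequent data.
#'
#' Identical configurations (including the seed) give identical cohorts, and
#' each participant draws from its own seeded substream, so increasing
#' `n_participants` leaves existing participants unchanged.
#'
#' @param config A [sim_config()].
#' @return A [vkr_cohort()]; KOOS values are clipped to `[0, 100]` after
#'   noise and the number of clipped values is recorded in `$n_clipped`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  if (n == 0L) return(empty_cohort())
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    parts[[i]] <- simulate_participant(i, config)
  }
  knees <- do.call(rbind, lapply(parts, `[[`, "knees"))
  visits <- do.call(rbind, lapply(parts, `[[`, "visits"))
  rownames(knees) <- rownames(visits) <- NULL
  vkr_cohort(knees, visits,
             n_clipped = sum(vapply(parts, `[[`, integer(1), "n_clipped")))
}

simulate_participant <- function(i, config) {
  months <- vkr_visit_months()
  pid <- sprintf("P%06d", i)
  sex <- if (stats::runif(1) < 0.52) "F" else "M"
  age <- clamp(stats::rnorm(1, 62.8, 9.3), 45, 79)
  bmi0 <- clamp(stats::rnorm(1, 29, 4.8), 16, 55)
  z_part <- stats::rnorm(1)
  kp_part <- stats::rnorm(1, 84, 7)
  qol_part <- stats::rnorm(1, 72, 9)
  coverage <- stats::runif(1) >= config$no_coverage_prob

  out_k <- vector("list", 2L)
  out_v <- vector("list", 2L)
  n_clip <- 0L
  for (s in 1:2) {
    side <- c("L", "R")[s]
    kn <- simulate_knee(pid, side, sex, age, bmi0, z_part, kp_part, qol_part,
                        coverage, config, months)
    out_k[[s]] <- kn$knee
    out_v[[s]] <- kn$visits
    n_clip <- n_clip + kn$n_clipped
  }
  list(
    knees = do.call(rbind, out_k),
    visits = do.call(rbind, out_v),
    n_clipped = n_clip
  )
}

simulate_knee <- function(pid, side, sex, age, bmi0, z_part, kp_part,
                          qol_part, coverage, config, months) {
  wpc <- config$within_person_corr
  rho <- config$symptom_structure_corr
  pf <- config$progressor_fraction
  z_sym <- sqrt(wpc) * z_part + sqrt(1 - wpc) * stats::rnorm(1)
  z_str <- rho * z_sym + sqrt(1 - rho^2) * stats::rnorm(1)
  z_cut <- if (pf > 0 && pf < 1) stats::qnorm(1 - pf) else if (pf >= 1) -Inf else Inf
  s_prog <- z_sym > z_cut
  g_case <- z_str > z_cut

  # baseline radiographic status
  klg <- if (stats::runif(1) < config$klg_missing_prob) {
    NA_integer_
  } else {
    sample(0:4, 1L, prob = config$klg_probs)
  }
  klg_for_jsn <- if (is.na(klg)) 1L else klg
  jsn_medial <- as.integer(clamp(klg_for_jsn - 1L + sample(c(-1L, 0L, 0L, 1L), 1L), 0L, 3L))
  jsn_lateral <- as.integer(clamp(jsn_medial - sample(0:2, 1L), 0L, 3L))

  # surgical KR hazard rises with the latent symptom score
  p_kr <- stats::plogis(-4.3 + 0.9 * z_sym)
  kr_month <- if (stats::runif(1) < p_kr) {
    sample(c(6L, 12L, 18L, 24L, 30L, 36L, 42L, 48L, 54L, 60L), 1L)
  } else NA_integer_

  # symptom trajectories: slow decline + progressor-specific steepening
  kp_bl <- kp_part + stats::rnorm(1, 0, 4)
  qol_bl <- qol_part + stats::rnorm(1, 0, 5)
  slope_kp <- -(0.5 + stats::runif(1, 0, 0.8))   # points per year
  slope_q <- -(0.5 + stats::runif(1, 0, 0.8))
  d_kp <- if (s_prog) max(10, 24 + 6 * max(z_sym - z_cut, 0) + stats::rnorm(1, 0, 4)) else 0
  d_q <- if (s_prog) max(10, 22 + 5 * max(z_sym - z_cut, 0) + stats::rnorm(1, 0, 4)) else 0
  maintain <- stats::runif(1) < config$maintain_prob
  ramp <- clamp((months - 36) / 24, 0, 1)        # 0 before 36 M, 1 at 60 M
  kp <- kp_bl + slope_kp * months / 12 - d_kp * ramp
  qol <- qol_bl + slope_q * months / 12 - d_q * ramp
  if (s_prog) {
    i72 <- which(months == 72L)
    if (maintain) {
      kp[i72] <- kp[i72] - stats::runif(1, 1, 5)
      qol[i72] <- qol[i72] - stats::runif(1, 1, 5)
    } else {
      kp[i72] <- kp[i72] + stats::runif(1, 6, 14)
      qol[i72] <- qol[i72] + stats::runif(1, 6, 14)
    }
  }
  kp <- kp + stats::rnorm(length(months), 0, 2.5)
  qol <- qol + stats::rnorm(length(months), 0, 2.5)
  n_clipped <- sum(kp < 0 | kp > 100) + sum(qol < 0 | qol > 100)
  kp <- clamp(kp, 0, 100)
  qol <- clamp(qol, 0, 100)
  womac <- clamp(round((100 - kp) * 0.2 + stats::rnorm(length(months), 0, 1)), 0, 20)
  bmi <- clamp(bmi0 + cumsum(c(0, stats::rnorm(length(months) - 1L, 0, 0.3))), 14, 60)

  # cartilage: annual Gaussian increments per subregion, group-calibrated
  mdl <- subregion_change_model()
  mu2 <- if (g_case) config$case_loss_mean_2y else config$control_loss_mean_2y
  sd2 <- if (g_case) config$case_loss_sd_2y else config$control_loss_sd_2y
  inc_mean <- mdl$frac * mu2 / 2
  inc_sd <- mdl$sd_scale * sd2 / 2
  n_int <- length(months) - 1L
  inc <- matrix(
    stats::rnorm(16L * n_int, mean = rep(inc_mean, n_int), sd = rep(inc_sd, n_int)),
    nrow = 16L
  )
  base_th <- subregion_baseline_means() * exp(stats::rnorm(1, 0, 0.08)) *
    exp(stats::rnorm(16L, 0, 0.05))
  th <- cbind(base_th, base_th + t(apply(inc, 1L, cumsum)))
  th <- pmax(th, 0)

  mjsw0 <- clamp(stats::rnorm(1, 4.0, 1.9), 0.5, 8)
  mjsw_mu <- if (g_case) -0.458 / 2 else -0.278 / 2      # mm per year
  mjsw_sd <- if (g_case) 0.663 / sqrt(2) else 0.743 / sqrt(2)
  mjsw <- pmax(mjsw0 + cumsum(c(0, stats::rnorm(n_int, mjsw_mu, mjsw_sd))), 0)

  baseline_koos_na <- stats::runif(1) < config$baseline_koos_missing_prob
  if (baseline_koos_na) {
    kp[1] <- NA_real_
    qol[1] <- NA_real_
  }

  knee_id <- paste0(pid, "_", side)
  visits <- data.frame(
    knee_id = knee_id, visit_month = months, pro_present = TRUE,
    koos_pain = kp, koos_qol = qol, womac_pain = womac, bmi = bmi,
    cart_readable = TRUE, stringsAsFactors = FALSE
  )
  th_df <- as.data.frame(t(th))
  names(th_df) <- thickness_columns()
  visits <- cbind(visits, th_df)
  visits$mjsw_medial <- mjsw

  # no data after a surgical KR
  if (!is.na(kr_month)) {
    gone <- visits$visit_month > kr_month
    visits$pro_present[gone] <- FALSE
    visits$cart_readable[gone] <- FALSE
    visits[gone, c("koos_pain", "koos_qol", "womac_pain", "bmi",
                   thickness_columns(), "mjsw_medial")] <- NA_real_
  }

  knee <- data.frame(
    knee_id = knee_id, participant_id = pid, side = side, sex = sex,
    age_baseline = age, klg = klg, klg_stratum = klg_to_stratum(klg),
    jsn_medial = jsn_medial, jsn_lateral = jsn_lateral,
    jsn_dominant = jsn_dominant_compartment(jsn_medial, jsn_lateral),
    surgical_kr_month = kr_month, continuous_coverage = coverage,
    symptom_progressor = s_prog, structure_case = g_case,
    latent_symptom = z_sym, latent_structure = z_str,
    stringsAsFactors = FALSE
  )
  list(knee = knee, visits = visits, n_clipped = as.integer(n_clipped))
}

#' Inject visit-level missingness
#'
#' Marks PRO visits as missed and cartilage images as unreadable,
#' independently per visit with probability `missing_visit_prob`, never at
#' month 0. Each knee uses its own seeded substream derived from the config
#' seed, so the pattern is reproducible and stable under cohort growth.
#'
#' @param cohort A [vkr_cohort()].
#' @param config The [sim_config()] providing `missing_visit_prob` and `seed`.
#' @return The cohort with updated presence/readability flags (values at
#'   missed visits set to NA).
#' @export
inject_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "vkr_cohort"))
  validate_sim_config(config)
  p <- config$missing_visit_prob
  if (p == 0 || nrow(cohort$visits) == 0L) return(cohort)
  v <- cohort$visits
  for (id in cohort$knees$knee_id) {
    set.seed(substream_seed(config$seed + 1000003L, string_key(id)))
    rows <- which(v$knee_id == id & v$visit_month > 0L)
    if (length(rows) == 0L) next
    drop_pro <- stats::runif(length(rows)) < p
    drop_cart <- stats::runif(length(rows)) < p
    pro_rows <- rows[drop_pro & v$pro_present[rows]]
    cart_rows <- rows[drop_cart & v$cart_readable[rows]]
    v$pro_present[pro_rows] <- FALSE
    v[pro_rows, c("koos_pain", "koos_qol", "womac_pain", "bmi")] <- NA_real_
    v$cart_readable[cart_rows] <- FALSE
    v[cart_rows, c(thickness_columns(), "mjsw_medial")] <- NA_real_
  }
  cohort$visits <- v
  cohort
}

#' Draw matched two-year cartilage changes from the generator's model
#'
#' Convenience sampler used for power/calibration studies: draws `n_pairs`
#' case knees and `n_pairs` control knees and returns their two-year cMFTC
#' thickness changes, built exactly as in [generate_cohort()] -- four
#' independent annual Gaussian increments (two years by two central medial
#' subregions) per knee, calibrated to the configured group means/SDs.
#'
#' @param n_pairs Number of case-control pairs.
#' @param config A [sim_config()] supplying the group change distributions.
#' @param seed Integer seed.
#' @return Data frame with columns `case_change` and `control_change`
#'   (micrometres, negative = loss).
#' @export
simulate_matched_changes <- function(n_pairs, config = sim_config(), seed = 1L) {
  stopifnot(n_pairs >= 1L)
  set.seed(substream_seed(seed, 424243L))
  mdl <- subregion_change_model()
  central <- c("cMT", "ccMF")
  draw <- function(mu2, sd2) {
    inc_mean <- mdl$frac[central] * mu2 / 2
    inc_sd <- mdl$sd_scale[central] * sd2 / 2
    # 4 increments per knee: 2 years x 2 central medial subregions
    m <- matrix(
      stats::rnorm(4L * n_pairs, mean = rep(rep(inc_mean, each = 1L), each = 2L),
                   sd = rep(rep(inc_sd, each = 1L), each = 2L)),
      nrow = 4L
    )
    colSums(m)
  }
  data.frame(
    case_change = draw(config$case_loss_mean_2y, config$case_loss_sd_2y),
    control_change = draw(config$control_loss_mean_2y, config$control_loss_sd_2y)
  )
}
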