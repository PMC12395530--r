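# Fixture builders: hand-constructed knees with fully specified PRO and
# cartilage series, assembled into valid vkr_cohort objects.

make_knee <- function(id = "K001_L", pid = sub("_[LR]$", "", id),
                      side = sub("^.*_", "", id), sex = "F", age = 60,
                      klg = 2L, jsn_medial = 1L, jsn_lateral = 0L,
                      kr_month = NA_integer_, coverage = TRUE,
                      kp = rep(80, 7), qol = rep(70, 7),
                      bmi = rep(27, 7), womac = rep(4, 7),
                      th = NULL, mjsw = rep(4, 7),
                      pro_present = NULL, cart_readable = rep(TRUE, 7)) {
  months <- vkr_visit_months()
  if (is.null(pro_present)) pro_present <- !is.na(kp)
  if (is.null(th)) th <- matrix(1500, nrow = 7, ncol = 16)
  if (is.vector(th) && length(th) == 16L) {
    th <- matrix(rep(th, each = 7), nrow = 7)
  }
  stopifnot(nrow(th) == 7L, ncol(th) == 16L)
  knee <- data.frame(
    knee_id = id, participant_id = pid, side = side, sex = sex,
    age_baseline = age, klg = klg, klg_stratum = vkr:::klg_to_stratum(klg),
    jsn_medial = jsn_medial, jsn_lateral = jsn_lateral,
    jsn_dominant = vkr:::jsn_dominant_compartment(jsn_medial, jsn_lateral),
    surgical_kr_month = kr_month, continuous_coverage = coverage,
    symptom_progressor = FALSE, structure_case = FALSE,
    latent_symptom = 0, latent_structure = 0, stringsAsFactors = FALSE
  )
  visits <- data.frame(
    knee_id = id, visit_month = months, pro_present = pro_present,
    koos_pain = ifelse(pro_present, kp, NA_real_),
    koos_qol = ifelse(pro_present, qol, NA_real_),
    womac_pain = ifelse(pro_present, womac, NA_real_),
    bmi = ifelse(pro_present, bmi, NA_real_),
    cart_readable = cart_readable, stringsAsFactors = FALSE
  )
  th_df <- as.data.frame(th)
  names(th_df) <- vkr:::thickness_columns()
  th_df[!cart_readable, ] <- NA_real_
  visits <- cbind(visits, th_df)
  visits$mjsw_medial <- ifelse(cart_readable, mjsw, NA_real_)
  list(knee = knee, visits = visits)
}

bind_cohort <- function(...) {
  ks <- list(...)
  vkr_cohort(
    do.call(rbind, lapply(ks, `[[`, "knee")),
    do.call(rbind, lapply(ks, `[[`, "visits"))
  )
}

# a knee whose trajectory first meets the vKR rule at the month-60 assessment
# (t0 = 48): flat and healthy through 36 M, steep drop at 48 M, sustained at
# 60 M and 72 M
make_progressor_knee <- function(id, sex = "F", age = 60, klg = 2L, ...) {
  make_knee(
    id = id, sex = sex, age = age, klg = klg,
    kp = c(80, 80, 80, 78, 50, 45, 43),
    qol = c(70, 70, 70, 69, 40, 40, 38),
    ...
  )
}

# a permanently healthy knee with top scores (never a case, ideal control)
make_healthy_knee <- function(id, sex = "F", age = 60, klg = 2L, ...) {
  make_knee(id = id, sex = sex, age = age, klg = klg,
            kp = rep(100, 7), qol = rep(100, 7), ...)
}

# independent literal transcription of the case-definition flowchart,
# deliberately scalar and branch-by-branch; used as the classifier oracle
fig2_oracle <- function(kp_t0, kp_tm1, qol_t0, qol_tm1,
                        kp_bl, qol_bl, kp_t1, qol_t1, threshold = 95.7,
                        qol_w = 0.54, worse_w = 1.06) {
  qol_max <- if (qol_t0 >= qol_tm1) qol_t0 else qol_tm1
  if (kp_t0 < kp_tm1) {
    score <- kp_t0 + qol_w * qol_max - worse_w * abs(kp_tm1 - kp_t0)
  } else {
    score <- kp_t0 + qol_w * qol_max
  }
  cond1 <- score < threshold
  cond2 <- (kp_t0 < kp_bl) && (qol_t0 < qol_bl)
  cond3 <- (kp_t1 <= kp_t0) && (qol_t1 <= qol_t0)
  list(score = score, is_case = cond1 && cond2 && cond3,
       branch = if (kp_t0 < kp_tm1) "pain_worse" else "pain_not_worse")
}

# brute-force maximiser of the written 1:1 conditional likelihood (1-d)
clogit_brute <- function(d) {
  ll <- function(b) sum(-log1p(exp(-b * d)))
  stats::optimize(ll, c(-30, 30), maximum = TRUE, tol = 1e-10)$maximum
}
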