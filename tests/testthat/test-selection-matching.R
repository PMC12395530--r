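test_that("the exclusion cascade removes one knee per reason, in order", {
  knees <- list(
    make_knee("K001_L", kr_month = 6L),                                 # KR before 12 M
    make_knee("K002_L", pro_present = c(TRUE, FALSE, rep(TRUE, 5))),    # no 12 M follow-up
    make_knee("K003_L", coverage = FALSE),
    make_knee("K004_L", pro_present = c(FALSE, rep(TRUE, 6))),          # no baseline KOOS
    make_knee("K005_L", klg = NA_integer_),
    make_knee("K006_L"), make_knee("K007_L"), make_knee("K008_L"),
    make_knee("K009_L"), make_knee("K010_L")
  )
  co <- do.call(bind_cohort, knees)
  rep <- apply_exclusion_cascade(co)
  expect_equal(rep$steps$n_removed, rep(1L, 5))
  expect_equal(tail(rep$steps$n_remaining, 1), 5L)
  expect_setequal(rep$eligible, sprintf("K%03d_L", 6:10))

  # a knee hit by several reasons is counted once, at the first step
  multi <- make_knee("K011_L", kr_month = 6L, coverage = FALSE, klg = NA_integer_)
  co2 <- do.call(bind_cohort, c(knees, list(multi)))
  rep2 <- apply_exclusion_cascade(co2)
  expect_equal(rep2$steps$n_removed, c(2L, 1L, 1L, 1L, 1L))
  expect_equal(rep2$n_initial - sum(rep2$steps$n_removed),
               tail(rep2$steps$n_remaining, 1))
})

test_that("an all-clean cohort passes the cascade untouched", {
  co <- bind_cohort(make_knee("K001_L"), make_knee("K002_L"))
  rep <- apply_exclusion_cascade(co)
  expect_equal(sum(rep$steps$n_removed), 0L)
  expect_equal(length(rep$eligible), 2L)
})

test_that("cascade reports must reconcile step by step", {
  steps <- data.frame(step = c("a", "b"), n_removed = c(2L, 3L),
                      n_remaining = c(8L, 5L))
  rep <- new_cascade_report(steps, n_initial = 10L)
  expect_s3_class(rep, "cascade_report")
  bad <- steps
  bad$n_remaining <- c(8L, 4L)
  expect_error(new_cascade_report(bad, n_initial = 10L), "reconcile")
  bad2 <- steps
  bad2$n_removed <- c(-1L, 3L)
  expect_error(new_cascade_report(bad2, n_initial = 10L), "non-negative")
})

test_that("case selection keeps only month-60 first-time cases with full MRI", {
  planted <- lapply(sprintf("C%03d_L", 1:5), make_progressor_knee)
  healthy <- lapply(sprintf("H%03d_L", 1:5), make_healthy_knee)
  # case already at 48 M (earlier first case) must be excluded
  early <- make_knee("E001_L",
                     kp = c(80, 80, 70, 55, 50, 45, 43),
                     qol = c(70, 70, 60, 40, 38, 36, 34))
  # a 60 M case with an unreadable 36 M image must be excluded
  no_mri <- make_progressor_knee("M001_L")
  no_mri$visits$cart_readable[no_mri$visits$visit_month == 36] <- FALSE
  no_mri$visits[no_mri$visits$visit_month == 36,
                c(vkr:::thickness_columns(), "mjsw_medial")] <- NA_real_
  co <- do.call(bind_cohort, c(planted, healthy, list(early, no_mri)))
  rep <- apply_exclusion_cascade(co)
  cases <- select_cases(co, rep$eligible)
  expect_setequal(cases, sprintf("C%03d_L", 1:5))
})

test_that("control selection keeps the lowest-risk fifth and honours contralateral exclusions", {
  # 1000 knees with distinct composite scores (unique KOOS pain levels)
  n <- 1000
  kp_levels <- seq(30, 99.9, length.out = n)
  knees <- lapply(seq_len(n), function(i) {
    make_knee(sprintf("K%04d_L", i), kp = rep(kp_levels[i], 7),
              qol = rep(50, 7))
  })
  co <- do.call(bind_cohort, knees)
  ctrl <- select_controls(co, co$knees$knee_id, cases = character())
  expect_length(ctrl, 200)
  # the selected knees are exactly the 200 highest scores
  expect_setequal(ctrl, sprintf("K%04d_L", (n - 199):n))

  # contralateral case knee disqualifies a control
  case_l <- make_progressor_knee("P001_L")
  ctrl_r <- make_healthy_knee("P001_R")
  others <- lapply(sprintf("P%03d_L", 2:8), make_healthy_knee)
  bad <- make_knee("P009_L", kp = rep(50, 7), qol = rep(40, 7))
  co2 <- do.call(bind_cohort, c(list(case_l, ctrl_r), others, list(bad)))
  cases2 <- select_cases(co2, co2$knees$knee_id)
  expect_equal(cases2, "P001_L")
  ctrl2 <- select_controls(co2, co2$knees$knee_id, cases2)
  expect_false("P001_R" %in% ctrl2)
  expect_true("P002_L" %in% ctrl2)
  expect_false("P009_L" %in% ctrl2)
})

test_that("greedy matching respects strata, caliper and processing order", {
  frame <- function(id, sex = "F", age, klg = "2", jsn = "medial",
                    pid = sub("_[LR]$", "", id)) {
    data.frame(knee_id = id, participant_id = pid, sex = sex, age = age,
               klg_stratum = klg, jsn_dominant = jsn, stringsAsFactors = FALSE)
  }
  # one case, one compatible control 4 years apart
  m <- match_pairs(frame("A_L", age = 60), frame("B_L", age = 64))
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$age_gap, 4)

  # only control 6 years apart: outside the caliper
  m2 <- match_pairs(frame("A_L", age = 60), frame("B_L", age = 66))
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched, "A_L")

  # greedy order: the younger case takes the near control, leaving the
  # second case with only an out-of-caliper candidate
  cases <- rbind(frame("A1_L", age = 60), frame("A2_L", age = 62))
  ctrls <- rbind(frame("B1_L", age = 61), frame("B2_L", age = 70))
  m3 <- match_pairs(cases, ctrls)
  expect_equal(m3$pairs$case_knee_id, "A1_L")
  expect_equal(m3$pairs$control_knee_id, "B1_L")
  expect_equal(m3$unmatched, "A2_L")

  # stratum mismatch blocks a match even at age 0 gap
  m4 <- match_pairs(frame("A_L", age = 60, klg = "2"),
                    frame("B_L", age = 60, klg = "3"))
  expect_equal(m4$unmatched, "A_L")

  expect_error(match_pairs(frame("A_L", age = 60), frame("B_L", age = 60),
                           age_caliper = 0), "positive")
})

test_that("matching is deterministic, never reuses controls, and satisfies constraints", {
  set.seed(99)
  mk <- function(prefix, n) {
    data.frame(
      knee_id = sprintf("%s%03d_L", prefix, seq_len(n)),
      participant_id = sprintf("%s%03d", prefix, seq_len(n)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = runif(n, 50, 75),
      klg_stratum = sample(c("0-1", "2", "3"), n, replace = TRUE),
      jsn_dominant = sample(c("none", "medial", "lateral"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  cases <- mk("C", 40)
  ctrls <- mk("K", 120)
  m1 <- match_pairs(cases, ctrls, seed = 11)
  m2 <- match_pairs(cases, ctrls, seed = 11)
  expect_identical(m1, m2)
  p <- m1$pairs
  expect_false(any(duplicated(p$control_knee_id)))
  expect_true(all(p$age_gap <= 5))
  ci <- match(p$case_knee_id, cases$knee_id)
  ki <- match(p$control_knee_id, ctrls$knee_id)
  expect_equal(cases$sex[ci], ctrls$sex[ki])
  expect_equal(cases$klg_stratum[ci], ctrls$klg_stratum[ki])
  expect_equal(cases$jsn_dominant[ci], ctrls$jsn_dominant[ki])
})

test_that("every case with an in-caliper stratum partner gets matched", {
  cases <- data.frame(
    knee_id = sprintf("C%02d_L", 1:10), participant_id = sprintf("C%02d", 1:10),
    sex = "F", age = seq(55, 64), klg_stratum = "2", jsn_dominant = "medial",
    stringsAsFactors = FALSE
  )
  ctrls <- cases
  ctrls$knee_id <- sub("^C", "K", ctrls$knee_id)
  ctrls$participant_id <- sub("^C", "K", ctrls$participant_id)
  ctrls$age <- ctrls$age + 1
  m <- match_pairs(cases, ctrls)
  expect_length(m$unmatched, 0)
  expect_equal(nrow(m$pairs), 10L)
})

test_that("radiographic derivations follow the stratum and dominance rules", {
  expect_equal(vkr:::klg_to_stratum(c(0L, 1L, 2L, 3L, 4L, NA)),
               c("0-1", "0-1", "2", "3", "4", NA))
  expect_equal(vkr:::jsn_dominant_compartment(c(0L, 2L, 1L, 2L), c(0L, 2L, 2L, 1L)),
               c("none", "both", "lateral", "medial"))
})
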