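test_that("paired t-test matches hand arithmetic and rejects degenerate input", {
  # alternating differences cancel: t = 0, p = 1
  out <- paired_t(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  # d = (1, 2, 3): mean 2, sd 1, t = 2 / (1/sqrt(3))
  out2 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(out2$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(out2$df, 2)
  expect_error(paired_t(5, 3), "at least 2")
  expect_error(paired_t(c(3, 4), c(1, 2)), "identical")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("conditional logistic estimate matches brute-force likelihood maximisation", {
  # symmetric differences: beta = 0, OR = 1
  fit <- clogit_1to1(c(1, -1, 1, -1), c(0, 0, 0, 0), scale_sd = 1)
  expect_equal(fit$beta[[1]], 0, tolerance = 1e-8)
  expect_equal(fit$or_per_sd, 1, tolerance = 1e-8)

  # monotone likelihood is reported as separation, not "fixed"
  expect_error(clogit_1to1(c(1, 1, 1), c(0, 0, 0), scale_sd = 1), "separation")
  expect_error(clogit_1to1(c(0, 0), c(1, 1), scale_sd = 1), "separation")

  # the documented instance: differences (2, 2, -1)
  fit2 <- clogit_1to1(c(2, 2, -1), c(0, 0, 0), scale_sd = 1)
  expect_equal(fit2$beta[[1]], clogit_brute(c(2, 2, -1)), tolerance = 1e-6)

  # random small instances against the brute-force oracle
  set.seed(31)
  done <- 0
  while (done < 25) {
    n <- sample(2:5, 1)
    d <- sample(-3:3, n, replace = TRUE)
    if (all(d >= 0) || all(d <= 0)) next
    fit3 <- clogit_1to1(d, rep(0, n), scale_sd = 1)
    expect_equal(fit3$beta[[1]], clogit_brute(d), tolerance = 1e-6)
    done <- done + 1
  }
})

test_that("odds ratio per control-SD is invariant to common rescaling", {
  set.seed(32)
  x_case <- rnorm(50, 0.4)
  x_ctrl <- rnorm(50)
  s <- sd(x_ctrl)
  f1 <- clogit_1to1(x_case, x_ctrl, scale_sd = s)
  for (c_mult in c(0.01, 3.7, 1000)) {
    f2 <- clogit_1to1(c_mult * x_case, c_mult * x_ctrl, scale_sd = c_mult * s)
    expect_equal(f2$or_per_sd, f1$or_per_sd, tolerance = 1e-10)
    expect_equal(f2$se_robust, f1$se_robust, tolerance = 1e-8)
  }
})

test_that("estimates and cluster-robust variance agree with survival::clogit", {
  set.seed(33)
  n <- 120
  # 40 participants contribute two case knees each to different pairs
  case_part <- rep(sprintf("P%02d", 1:40), length.out = n)
  u <- rnorm(40)[match(case_part, sprintf("P%02d", 1:40))]
  x_case <- 0.8 * u + rnorm(n)
  x_ctrl <- rnorm(n)
  ctrl_part <- sprintf("Q%03d", seq_len(n))
  fit <- clogit_1to1(x_case, x_ctrl, scale_sd = 1,
                     case_cluster = case_part, control_cluster = ctrl_part)

  library(survival)
  # the sandwich clusters whole pairs by their shared participant, so the
  # matching survival specification clusters both knees of a pair on the
  # case participant (controls here are all distinct)
  df <- data.frame(
    y = rep(c(1, 0), each = n), x = c(x_case, x_ctrl),
    pair = rep(seq_len(n), 2), part = rep(case_part, 2)
  )
  # one case per stratum: efron/breslow/exact partial likelihoods coincide,
  # and only the non-exact methods support the robust variance
  sf <- survival::clogit(y ~ x + strata(pair) + cluster(part), data = df,
                         method = "efron")
  expect_equal(fit$beta[[1]], unname(coef(sf)), tolerance = 1e-6)
  expect_equal(fit$se_robust[[1]], sqrt(unname(vcov(sf)[1, 1])), tolerance = 1e-4)

  # model-based variance agrees with an unclustered fit
  sf0 <- survival::clogit(y ~ x + strata(pair), data = df)
  expect_equal(fit$se_model[[1]], sqrt(unname(vcov(sf0)[1, 1])), tolerance = 1e-6)
})

test_that("BMI categories use half-open WHO bounds and difference coding", {
  expect_equal(unname(bmi_adjustment_covariates(24, 24)), matrix(c(0, 0), 1))
  expect_equal(unname(bmi_adjustment_covariates(31, 26)), matrix(c(-1, 1), 1))
  expect_equal(unname(bmi_adjustment_covariates(25, 24.9)), matrix(c(1, 0), 1))
  expect_equal(unname(bmi_adjustment_covariates(30, 29.9)), matrix(c(-1, 1), 1))
  expect_error(bmi_adjustment_covariates(-1, 25), "positive")
})

test_that("adjusted fit accepts covariate differences", {
  set.seed(34)
  n <- 80
  x_case <- rnorm(n, 0.5)
  x_ctrl <- rnorm(n)
  cov_d <- bmi_adjustment_covariates(runif(n, 20, 35), runif(n, 20, 35))
  fit <- clogit_1to1(x_case, x_ctrl, scale_sd = 1, covariate_diffs = cov_d)
  expect_length(fit$beta, 3)
  expect_true(fit$converged)
})

test_that("Kruskal-Wallis handles exchangeable, shifted and degenerate groups", {
  out <- kruskal_wallis(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$H, 0, tolerance = 1e-12)
  expect_equal(out$p, 1)
  out2 <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out2$H, 3.8571, tolerance = 1e-4)
  out3 <- kruskal_wallis(rep(7, 4), rep(7, 3))
  expect_equal(out3$H, 0)
  expect_equal(out3$p, 1)
  expect_error(kruskal_wallis(numeric(), 1:3), "non-empty")
})

test_that("tied-data Kruskal-Wallis agrees with a permutation test", {
  set.seed(35)
  a <- sample(1:4, 35, replace = TRUE)
  b <- sample(2:5, 30, replace = TRUE)
  kw <- kruskal_wallis(a, b)
  pooled <- c(a, b)
  n_a <- length(a)
  stat <- function(idx) kruskal_wallis(pooled[idx], pooled[-idx])$H
  perm <- replicate(4000, stat(sample(length(pooled), n_a)))
  p_perm <- mean(perm >= kw$H - 1e-12)
  expect_lt(abs(p_perm - kw$p), 0.03)
})

test_that("comparison table composes the individual operations", {
  expect_equal(nrow(build_table(bind_cohort(make_knee()), NULL)), 0)

  set.seed(36)
  knees <- list()
  for (i in 1:6) {
    th_c <- matrix(rnorm(7 * 16, 1500, 30), nrow = 7)
    th_k <- matrix(rnorm(7 * 16, 1500, 30), nrow = 7)
    knees[[2 * i - 1]] <- make_knee(sprintf("C%02d_L", i), th = th_c)
    knees[[2 * i]] <- make_knee(sprintf("K%02d_L", i), th = th_k)
  }
  co <- do.call(bind_cohort, knees)
  pairs <- data.frame(
    case_knee_id = sprintf("C%02d_L", 1:6),
    control_knee_id = sprintf("K%02d_L", 1:6),
    case_participant_id = sprintf("C%02d", 1:6),
    control_participant_id = sprintf("K%02d", 1:6),
    stringsAsFactors = FALSE
  )
  tb <- build_table(co, pairs, regions = "cMFTC", intervals = list(c(24L, 48L)),
                    include_scores = FALSE)
  expect_equal(nrow(tb), 1L)
  dc <- sapply(pairs$case_knee_id, function(id)
    interval_change(knee_series(co, id), "cMFTC", 24, 48)$delta)
  dk <- sapply(pairs$control_knee_id, function(id)
    interval_change(knee_series(co, id), "cMFTC", 24, 48)$delta)
  expect_equal(tb$case_mean, mean(dc))
  expect_equal(tb$control_sd, sd(dk))
  tt <- paired_t(dc, dk)
  expect_equal(tb$t_stat, tt$t)
  fit <- clogit_1to1(-dc, -dk, scale_sd = sd(dk),
                     case_cluster = pairs$case_participant_id,
                     control_cluster = pairs$control_participant_id)
  expect_equal(tb$or_per_sd, fit$or_per_sd)
  expect_equal(tb$ci_low, fit$ci_low)
})

test_that("maintenance comparison splits cases and drops knees without 72 M data", {
  sustained <- make_knee("S001_L", kp = c(80, 80, 80, 78, 50, 45, 43),
                         qol = c(70, 70, 70, 69, 40, 40, 38))
  rebound <- make_knee("R001_L", kp = c(80, 80, 80, 78, 50, 45, 60),
                       qol = c(70, 70, 70, 69, 40, 40, 55))
  no72 <- make_knee("N001_L", kp = c(80, 80, 80, 78, 50, 45, NA),
                    qol = c(70, 70, 70, 69, 40, 40, NA))
  co <- bind_cohort(sustained, rebound, no72)
  out <- maintenance_comparison(co, c("S001_L", "R001_L", "N001_L"),
                                regions = "cMFTC")
  expect_equal(out$dropped, "N001_L")
  expect_equal(unname(out$status["S001_L"]), "vKR+/+")
  expect_equal(unname(out$status["R001_L"]), "vKR+/-")
  expect_equal(out$table$n_maintained, 1L)
  expect_equal(out$table$n_not_maintained, 1L)
})
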