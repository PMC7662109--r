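test_that("dataset construction enforces the longitudinal invariants", {
  d <- data.frame(patient_id = c("a", "a", "b", "b", "c"),
                  time_months = c(0, 12, 0, 6, 0),
                  outcome = c(1, 2, 3, 4, 5))
  expect_message(ld <- longitudinal_dataset(d), "single scan")
  expect_equal(sort(unique(ld$patient_id)), c("a", "b"))

  expect_error(longitudinal_dataset(
    data.frame(patient_id = c("a", "a"), time_months = c(-1, 2),
               outcome = 1:2)), "nonnegative")
  expect_error(longitudinal_dataset(
    data.frame(patient_id = rep("a", 3), time_months = c(0, 5, 5),
               outcome = 1:3)), "strictly increasing|at least 2 patients")
  expect_error(longitudinal_dataset(
    data.frame(patient_id = c("a", "a"), time_months = c(0, 5),
               outcome = 1:2)), "at least 2 patients")
})

test_that("noise-free linear data is recovered exactly", {
  d <- data.frame(patient_id = rep(1:5, each = 4),
                  time_months = rep(c(0, 6, 12, 24), 5))
  d$outcome <- 2 + 0.5 * d$time_months
  fit <- suppressWarnings(fit_trend(d, nonlinearity = FALSE))
  expect_equal(fit$slope, 0.5, tolerance = 1e-6)
  expect_equal(fit$intercept, 2, tolerance = 1e-6)
  expect_lt(fit$sigma_residual, 1e-4)
})

test_that("sqrt transform equals fitting identity on pre-transformed data", {
  d <- simulate_score_trajectories(n_patients = 20, slope = 0.1,
                                   intercept = 25, seed = 4)
  d$outcome <- abs(d$outcome)
  f1 <- fit_trend(d, transform = "sqrt", nonlinearity = FALSE)
  d2 <- d; d2$outcome <- sqrt(d$outcome)
  f2 <- fit_trend(d2, transform = "identity", nonlinearity = FALSE)
  expect_identical(f1$slope, f2$slope)
  expect_identical(f1$se, f2$se)
  expect_identical(f1$p_value, f2$p_value)
  d$outcome[1] <- -1
  expect_error(fit_trend(d, transform = "sqrt"), "nonnegative")
})

test_that("time shifts move the intercept, not the slope", {
  d <- simulate_score_trajectories(n_patients = 25, slope = 0.15, seed = 9)
  f1 <- fit_trend(d, nonlinearity = FALSE)
  d2 <- d; d2$time_months <- d2$time_months + 7
  f2 <- fit_trend(d2, nonlinearity = FALSE)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
  expect_equal(f2$intercept, f1$intercept - 7 * f1$slope, tolerance = 1e-4)
})

test_that("LMM and GEE engines concur on balanced data", {
  set.seed(31)
  n <- 120
  d <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- c(0, 12, 24, 36)
    data.frame(patient_id = i, time_months = t,
               outcome = 10 + rnorm(1, 0, 6) + 0.2 * t + rnorm(4, 0, 4))
  }))
  f_lmm <- fit_trend(d, engine = "lmm", nonlinearity = FALSE)
  f_gee <- fit_trend(d, engine = "gee", nonlinearity = FALSE)
  expect_equal(f_lmm$slope, f_gee$slope, tolerance = 0.01)
  expect_equal(f_lmm$se, f_gee$se, tolerance = 0.1)
})

test_that("slope is recovered at the study-like design", {
  d <- simulate_score_trajectories(n_patients = 81, slope = 0.2,
                                   intercept = 15, seed = 12)
  for (eng in c("lmm", "gee")) {
    fit <- fit_trend(d, engine = eng, nonlinearity = FALSE)
    expect_equal(fit$slope, 0.2, tolerance = 0.15)
    expect_lt(fit$p_value, 0.001)
  }
})

test_that("prediction curve is linear in time with a finite 95% band", {
  d <- simulate_score_trajectories(n_patients = 30, slope = 0.1, seed = 3)
  fit <- fit_trend(d, nonlinearity = FALSE)
  cv <- fit$curve
  slopes <- diff(cv$fit) / diff(cv$time_months)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-9)
  expect_true(all(cv$lower < cv$fit & cv$fit < cv$upper))
  # monotone because the fitted model is linear with positive slope
  expect_true(all(diff(cv$fit) > 0))
})

test_that("nonlinearity test requires enough distinct times and detects curvature", {
  d2 <- data.frame(patient_id = rep(1:3, each = 2),
                   time_months = rep(c(0, 12), 3), outcome = rnorm(6))
  expect_error(test_nonlinearity(d2), "distinct time")

  set.seed(44)
  d <- do.call(rbind, lapply(1:40, function(i) {
    t <- c(0, 6, 12, 24, 36, 48)
    data.frame(patient_id = i, time_months = t,
               outcome = 5 + rnorm(1, 0, 1) + 0.01 * t^2 + rnorm(6, 0, 0.5))
  }))
  p <- test_nonlinearity(d)
  expect_lt(as.numeric(p), 0.001)
  expect_equal(attr(p, "df"), 2)

  # strongly quadratic, low noise: rejected in nearly all replicates
  rej <- vapply(1:20, function(r) {
    set.seed(500 + r)
    dd <- do.call(rbind, lapply(1:30, function(i) {
      t <- c(0, 6, 12, 24, 36)
      data.frame(patient_id = i, time_months = t,
                 outcome = 5 + rnorm(1, 0, 1) + 0.008 * t^2 + rnorm(5, 0, 0.5))
    }))
    as.numeric(test_nonlinearity(dd)) < 0.05
  }, NA)
  expect_gt(mean(rej), 0.9)
})
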