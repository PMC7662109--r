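test_that("invalid configs are rejected", {
  expect_error(sim_config(prevalence = c(ggo = 1.2)), "prevalence")
  expect_error(sim_config(observer = list(confusion = -0.1)), "confusion")
  expect_error(sim_config(visit = list(counts = 1:3, probs = c(0.5, 0.5, 0.5))),
               "sum to 1")
  expect_error(sim_config(visit = list(counts = c(1, 12), probs = c(0.5, 0.5))),
               "1-9")
})

test_that("same seed gives byte-identical cohorts; different seed differs", {
  cfg <- sim_config(seed = 42, n_patients = 6)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_sheets(simulate_cohort(cfg), f1)
  write_sheets(simulate_cohort(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  f3 <- tempfile(fileext = ".csv")
  write_sheets(simulate_cohort(sim_config(seed = 43, n_patients = 6)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  unlink(c(f1, f2, f3))
})

test_that("growing the cohort does not reshuffle existing patients", {
  small <- simulate_cohort(sim_config(seed = 8, n_patients = 4))
  big <- simulate_cohort(sim_config(seed = 8, n_patients = 8))
  ids <- function(co) vapply(co$sheets, `[[`, "", "patient_id")
  keep <- ids(big) %in% unique(ids(small))
  expect_identical(lapply(big$sheets[keep], `[[`, "values"),
                   lapply(small$sheets, `[[`, "values"))
})

test_that("all emitted sheets validate against the schema", {
  for (m in c("baumann", "hartmann")) {
    co <- simulate_cohort(sim_config(seed = 13, method = m, n_patients = 5))
    for (sh in c(co$sheets, co$truth$sheets)) {
      expect_equal(nrow(validate_sheet(sh, co$schema)), 0)
    }
  }
})

test_that("zero prevalence yields an all-zero cohort and no GLILD phenotype", {
  no_disease <- setNames(numeric(16),
                         names(glildscore:::.default_prevalence))
  co <- simulate_cohort(zero_noise_config(seed = 3, n_patients = 6,
                                          prevalence = no_disease))
  vals <- unlist(lapply(co$sheets, function(s) s$values$value))
  expect_true(all(vals == 0))
  # with a noisy observer the underlying truth is still all-zero
  noisy <- simulate_cohort(sim_config(seed = 3, n_patients = 6,
                                      prevalence = no_disease))
  expect_true(all(unlist(lapply(noisy$truth$sheets,
                                function(s) s$values$value)) == 0))
  latest <- most_recent_sheets(co$truth$sheets)
  ph <- vapply(latest, function(s) phenotype(s, co$schema)$glild_positive, NA)
  expect_true(all(!ph))
})

test_that("zero observer noise copies the truth exactly into both observers", {
  co <- simulate_cohort(zero_noise_config(seed = 21, n_patients = 6))
  obs <- vapply(co$sheets, `[[`, "", "observer_id")
  o1 <- co$sheets[obs == "obs1"]; o2 <- co$sheets[obs == "obs2"]
  expect_identical(lapply(o1, `[[`, "values"), lapply(o2, `[[`, "values"))
  expect_identical(lapply(o1, `[[`, "values"),
                   lapply(co$truth$sheets, `[[`, "values"))

  # zero-noise fidelity: emitted sheets re-score exactly to ground truth
  for (i in seq_along(o1)) {
    st <- score_table(o1[[i]], co$schema)
    truth <- co$truth$scores[co$truth$scores$scan_id == o1[[i]]$scan_id, ]
    expect_equal(st$percent, truth$percent[match(st$score_label,
                                                 truth$score_label)])
  }
})

test_that("empirical prevalence converges to the configured prevalence", {
  cfg <- zero_noise_config(seed = 6, n_patients = 1500,
                           visit = list(counts = 1L, probs = 1))
  co <- simulate_cohort(cfg, truth_scores = FALSE)
  for (abn in c("ggo", "bronchiectasis", "cysts")) {
    pos <- vapply(co$truth$sheets, function(s)
      component_score(s, abn, co$schema)$percent > 0, NA)
    expect_equal(mean(pos), unname(cfg$prevalence[abn]), tolerance = 0.035)
  }
})

test_that("study-like preset matches the reference cohort shape", {
  cfg <- study_like_config(seed = 1)
  co <- simulate_cohort(cfg, truth_scores = FALSE)
  pid <- vapply(co$truth$sheets, `[[`, "", "patient_id")
  n_scans <- table(pid)
  expect_length(n_scans, 138)
  expect_equal(sum(n_scans >= 2), 81)
  expect_true(all(n_scans >= 1 & n_scans <= 9))
  # median inter-scan gap close to 12 months
  gaps <- unlist(lapply(split(vapply(co$truth$sheets, `[[`, 0, "time_months"),
                              pid), function(t) diff(sort(t))))
  expect_equal(median(gaps), 12, tolerance = 0.25)
})

test_that("simulated trajectories carry their true slope", {
  d <- simulate_score_trajectories(n_patients = 40, slope = 0.3, seed = 5)
  expect_equal(attr(d, "true_slope"), 0.3)
  visits <- table(d$patient_id)
  expect_true(all(visits >= 2 & visits <= 9))
  expect_true(all(d$time_months >= 0))
})
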