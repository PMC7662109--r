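b <- canonical_schema("baumann")
h <- canonical_schema("hartmann")

test_that("severity multipliers match the published tables", {
  expect_equal(multiplier("bronchiectasis", c(1, 1.5, 2, 2.5, 3)),
               c(1.00, 1.25, 1.50, 1.75, 2.00))
  expect_equal(multiplier("bronchial_wall_thickening", c(1, 2, 3)),
               c(1.00, 1.25, 1.50))
  expect_equal(multiplier("bronchiectasis", 0), 0)
  expect_error(multiplier("bronchiectasis", 1.2), "invalid")
  expect_error(multiplier("bronchial_wall_thickening", 1.5), "invalid")
  expect_error(multiplier("ggo", 1), "no multiplier table")
})

test_that("component scores reproduce hand-computed examples", {
  # 3 affected lobes at severity 2.0: 3 x 1.50 / (6 x 2.00) = 37.5%
  sh <- sheet_from_values(b, c(bronchiectasis_extent = 3,
                               bronchiectasis_severity = 2))
  expect_equal(component_score(sh, "bronchiectasis", b)$percent, 37.5)

  # maximal input saturates the scale
  shx <- sheet_from_values(b, c(bronchiectasis_extent = 6,
                                bronchiectasis_severity = 3))
  expect_equal(component_score(shx, "bronchiectasis", b)$percent, 100)

  # all-zero sheet scores 0 everywhere
  z <- sheet_from_values(h)
  for (abn in c("bronchiectasis", "ggo", "nodules")) {
    expect_equal(component_score(z, abn, h)$percent, 0)
  }
  expect_error(component_score(z, "scars_bands", h), "unknown abnormality")

  # Hartmann weighted component: one lobe extent 2 at severity 2.5
  sh2 <- sheet_from_values(h, c(`bronchiectasis_extent.RUL` = 2,
                                `bronchiectasis_severity.RUL` = 2.5))
  expect_equal(component_score(sh2, "bronchiectasis", h)$percent,
               100 * 2 * 1.75 / 36)
})

test_that("composite scores are exact sums of their constituents", {
  set.seed(41)
  for (sch in list(b, h)) {
    sh <- random_valid_sheet(sch)
    for (nm in c("glild", "airway", "total")) {
      cs <- composite_score(sh, nm, sch)
      expect_equal(cs$raw_score,
                   sum(vapply(cs$constituents, `[[`, 0, "raw_score")))
      expect_equal(cs$max_score,
                   sum(vapply(cs$constituents, `[[`, 0, "max_score")))
      expect_equal(cs$percent, 100 * cs$raw_score / cs$max_score)
    }
    g <- composite_score(sh, "glild", sch)
    expect_setequal(vapply(g$constituents, `[[`, "", "abnormality"),
                    c("ggo", "nodules", "reticulation"))
    a <- composite_score(sh, "airway", sch)
    expect_setequal(vapply(a$constituents, `[[`, "", "abnormality"),
                    c("bronchial_wall_thickening", "bronchiectasis",
                      "mucus_plugging"))
  }
  expect_error(composite_score(sheet_from_values(b), "parenchymal", b),
               "unknown composite")
})

test_that("airway-only disease leaves GLILD at zero and vice versa", {
  sh <- sheet_from_values(b, c(bronchiectasis_extent = 4,
                               bronchiectasis_severity = 1))
  expect_equal(composite_score(sh, "glild", b)$percent, 0)
  expect_gt(composite_score(sh, "airway", b)$percent, 0)
  ph <- phenotype(sh, b)
  expect_true(ph$airway_positive)
  expect_false(ph$glild_positive)

  sh2 <- sheet_from_values(b, c(nodules_extent = 2, nodule_size_category = 1))
  ph2 <- phenotype(sh2, b)
  expect_true(ph2$glild_positive)
  expect_equal(ph2$glild_features_present, "nodules")
  expect_false(ph2$airway_positive)

  z <- phenotype(sheet_from_values(b), b)
  expect_false(z$glild_positive)
  expect_false(z$airway_positive)
  expect_length(z$glild_features_present, 0)
})

test_that("trapped air is excluded from the total by default but restorable", {
  sh <- sheet_from_values(b, c(trapped_air_extent = 6))
  expect_equal(composite_score(sh, "total", b)$percent, 0)
  with_ta <- composite_score(sh, "total", b, exclusions = character(0))
  expect_gt(with_ta$percent, 0)
})

test_that("lymphadenopathy enlargement uses mm threshold (Baumann) or presence (Hartmann)", {
  sh9 <- sheet_from_values(b, c(lymph_node_mm = 9))
  sh10 <- sheet_from_values(b, c(lymph_node_mm = 10))
  expect_false(phenotype(sh9, b)$lymphadenopathy_enlarged)
  expect_true(phenotype(sh10, b)$lymphadenopathy_enlarged)
  expect_true(phenotype(sh10, b, ln_threshold_mm = 11)$lymphadenopathy_enlarged == FALSE)
  hp <- sheet_from_values(h, c(lymphadenopathy_presence = 1))
  expect_true(phenotype(hp, h)$lymphadenopathy_enlarged)
})

test_that("component and composite scores agree with the naive re-scorer", {
  set.seed(99)
  abns_b <- c("bronchiectasis", "bronchial_wall_thickening", "mucus_plugging",
              "nodules", "reticulation", "ggo", "consolidation")
  for (rep in 1:60) {
    for (sch in list(b, h)) {
      sh <- random_valid_sheet(sch)
      for (abn in abns_b) {
        expect_equal(component_score(sh, abn, sch)$percent,
                     naive_component_percent(sh, abn, sch$method_name))
      }
      for (nm in c("glild", "airway", "total")) {
        expect_equal(composite_score(sh, nm, sch)$percent,
                     naive_composite_percent(sh, nm, sch$method_name))
      }
    }
  }
})

test_that("increasing an item never decreases a score that includes it", {
  set.seed(7)
  for (sch in list(b, h)) {
    ext_items <- sch$items[sch$items$value_kind %in%
                             c("extent_lobe_count", "extent_grade"), ]
    for (rep in 1:20) {
      sh <- random_valid_sheet(sch)
      i <- sample(nrow(sh$values), 1)
      item <- sh$values$item_id[i]
      row <- sch$items[sch$items$item_id == item, ]
      set <- row$allowed_set[[1]]
      if (is.null(set)) next
      pos <- which(abs(set - sh$values$value[i]) < 1e-9)
      if (pos == length(set)) next
      abn <- row$abnormality
      if (!abn %in% ext_items$abnormality) next
      before <- composite_score(sh, "total", sch,
                                exclusions = character(0))$percent
      before_c <- tryCatch(component_score(sh, abn, sch)$percent,
                           error = function(e) NA)
      sh$values$value[i] <- set[pos + 1]
      after <- composite_score(sh, "total", sch,
                               exclusions = character(0))$percent
      after_c <- tryCatch(component_score(sh, abn, sch)$percent,
                          error = function(e) NA)
      expect_gte(after, before)
      if (is.finite(before_c)) expect_gte(after_c, before_c)
    }
  }
})

test_that("most-recent selection picks max time with lexicographic tie-break", {
  mk <- function(p, s, t) sheet_from_values(b, patient_id = p, scan_id = s,
                                            time_months = t)
  sheets <- list(mk("a", "s1", 0), mk("a", "s2", 24),
                 mk("c", "s1", 10), mk("c", "s9", 10), mk("c", "s3", 10))
  latest <- most_recent_sheets(sheets)
  expect_length(latest, 2)
  got <- vapply(latest, `[[`, "", "scan_id")
  names(got) <- vapply(latest, `[[`, "", "patient_id")
  expect_equal(got[["a"]], "s2")
  expect_equal(got[["c"]], "s9")
})

test_that("cohort report matches independent order statistics and edge cases", {
  expect_error(cohort_report(list(), b), "empty cohort")

  # single patient: median equals that patient's score, zero-width IQR
  sh <- sheet_from_values(b, c(ggo_extent = 3, ggo_subtype = 1))
  rep1 <- cohort_report(list(sh), b)
  ggo_row <- rep1$distribution[rep1$distribution$score_label == "ggo", ]
  expect_equal(ggo_row$median, 50)
  expect_equal(ggo_row$q1, ggo_row$q3)

  set.seed(11)
  co <- simulate_cohort(zero_noise_config(seed = 11, n_patients = 25))
  latest <- most_recent_sheets(co$truth$sheets)
  rep2 <- cohort_report(latest, b)

  # medians/quartiles against a brute-force sort-and-pick oracle
  pct <- vapply(latest, function(s) composite_score(s, "glild", b)$percent, 0)
  g <- rep2$distribution[rep2$distribution$score_label == "glild", ]
  expect_equal(g$median, round(median(pct), 1))
  expect_equal(g$q1, round(unname(quantile(pct, 0.25)), 1))
  expect_equal(g$min, round(min(pct), 1))

  # prevalence counts against direct positivity
  nod <- vapply(latest, function(s) component_score(s, "nodules", b)$percent, 0)
  pr <- rep2$prevalence[rep2$prevalence$score_label == "nodules", ]
  expect_equal(pr$n_positive, sum(nod > 0))

  # every-positive cohort reports 100%
  all_pos <- lapply(1:4, function(i)
    sheet_from_values(b, c(nodules_extent = i, nodule_size_category = 1),
                      patient_id = paste0("q", i)))
  rep3 <- cohort_report(all_pos, b)
  expect_equal(
    rep3$prevalence$percent_positive[rep3$prevalence$score_label == "nodules"],
    100)

  # venn regions partition the GLILD-positive patients
  expect_equal(sum(rep2$venn$n), rep2$venn$n_glild_positive[1])
})
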