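test_that("all 12 outcome rules classify boundary patients exactly as printed", {
  cohort <- boundary_cohort(list(
    list(sex = "M", uric_acid = 420),            # at threshold -> case
    list(sex = "M", uric_acid = 419.9),
    list(sex = "F", uric_acid = 360),
    list(sex = "F", uric_acid = 359.9),
    list(hba1c = 6.5), list(hba1c = 6.49),
    list(ldl_c = 3.4), list(ldl_c = 3.39),
    list(triglycerides = 2.3), list(triglycerides = 2.29),
    list(total_cholesterol = 6.2), list(total_cholesterol = 6.19),
    list(sbp = 140), list(sbp = 139),
    list(dbp = 90), list(dbp = 89),
    list(sex = "M", waistline = 90), list(sex = "M", waistline = 89.9),
    list(sex = "F", waistline = 85), list(sex = "F", waistline = 84.9),
    list(bmi = 28.1), list(bmi = 28.0)           # obesity is strictly >
  ))
  lab <- classify_outcomes(cohort)
  expect_equal(lab$hyperuricemia[1:4], c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(lab$diabetes[5:6], c(TRUE, FALSE))
  expect_equal(lab$hyper_ldl_c[7:8], c(TRUE, FALSE))
  expect_equal(lab$hypertriglyceridemia[9:10], c(TRUE, FALSE))
  expect_equal(lab$hypercholesterolemia[11:12], c(TRUE, FALSE))
  expect_equal(lab$high_sbp[13:14], c(TRUE, FALSE))
  expect_equal(lab$high_dbp[15:16], c(TRUE, FALSE))
  expect_equal(lab$abdominal_obesity[17:20], c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(lab$obesity[21:22], c(TRUE, FALSE))
  # composites on the same rows
  expect_equal(lab$hypertension[13:16], c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(lab$hyperlipidemia[7:12], c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("metabolic syndrome requires at least 3 of its 4 components", {
  mets3 <- list(sex = "M", waistline = 95, triglycerides = 3, sbp = 150)  # 3 of 4
  mets2 <- list(sex = "M", waistline = 95, triglycerides = 3)             # 2 of 4
  mets4 <- utils::modifyList(mets3, list(hba1c = 7))                      # 4 of 4
  lab <- classify_outcomes(boundary_cohort(list(mets3, mets2, mets4)))
  expect_equal(lab$metabolic_syndrome, c(TRUE, FALSE, TRUE))
})

test_that("adding a metabolic-syndrome component never revokes the label", {
  set.seed(31)
  for (i in 1:25) {
    base <- list(sex = sample(c("M", "F"), 1),
                 waistline = runif(1, 60, 110),
                 triglycerides = runif(1, 0.5, 4),
                 sbp = runif(1, 100, 170), dbp = runif(1, 60, 110),
                 hba1c = runif(1, 4, 9))
    lab0 <- classify_outcomes(boundary_cohort(list(base)))
    # force one more component on
    flips <- list(list(waistline = 120), list(triglycerides = 5),
                  list(sbp = 180), list(hba1c = 10))
    for (fl in flips) {
      lab1 <- classify_outcomes(boundary_cohort(list(utils::modifyList(base, fl))))
      expect_false(isTRUE(lab0$metabolic_syndrome) && !isTRUE(lab1$metabolic_syndrome))
    }
  }
})

test_that("composite invariants hold on randomly generated cohorts", {
  for (seed in c(7, 8)) {
    cfg <- study_config(n_subjects = 300, n_chemicals_gc = 2,
                        n_chemicals_lc = 2, regions = "A", seed = seed)
    lab <- classify_outcomes(generate_cohort(cfg))
    expect_identical(lab$hypertension, lab$high_sbp | lab$high_dbp)
    expect_identical(lab$hyperlipidemia,
                     lab$hyper_ldl_c | lab$hypertriglyceridemia |
                       lab$hypercholesterolemia)
    comp <- cbind(lab$abdominal_obesity, lab$hypertriglyceridemia,
                  lab$hypertension, lab$diabetes)
    expect_identical(lab$metabolic_syndrome, rowSums(comp) >= 3)
  }
})

test_that("missing clinical values propagate to NA labels, not FALSE", {
  cohort <- boundary_cohort(list(list(sex = "M")))
  cohort$hba1c <- NA
  lab <- classify_outcomes(cohort)
  expect_true(is.na(lab$diabetes))
  expect_false(is.na(lab$hypertension))
  expect_error(classify_outcomes(transform(cohort, sex = "X")),
               "unknown sex")
})

test_that("a covariate-identical control is matched to its case", {
  cfg <- study_config(n_subjects = 200, n_chemicals_gc = 2, n_chemicals_lc = 2,
                      regions = c("A", "B"), seed = 17)
  cohort <- generate_cohort(cfg)
  labels <- classify_outcomes(cohort)
  out <- "diabetes"
  # clone the first eligible case into a control row
  ok <- !is.na(labels$disease_count) & labels$disease_count <= 2
  case_row <- which(labels[[out]] & ok)[1]
  skip_if(is.na(case_row))
  clone <- cohort[case_row, ]
  clone$subject_id <- "CLONE"
  clone$hba1c <- 5.0   # not a case, everything else identical
  cohort2 <- rbind(cohort, clone)
  labels2 <- classify_outcomes(cohort2)
  ms <- match_controls(cohort2, labels2, out)
  pair <- ms$control_id[ms$case_id == cohort$subject_id[case_row]]
  expect_equal(pair, "CLONE")
})

test_that("greedy descending-score matching equals the exhaustive minimal assignment", {
  # scores: cases {0.9, 0.2}, controls {0.85, 0.25}
  score <- c(0.9, 0.2, 0.85, 0.25)
  case <- c(TRUE, TRUE, FALSE, FALSE)
  # independent oracle: enumerate both pairings
  d <- abs(outer(score[case], score[!case], "-"))
  pairings <- list(c(1, 2), c(2, 1))
  costs <- sapply(pairings, function(p) d[1, p[1]] + d[2, p[2]])
  best <- pairings[[which.min(costs)]]
  # greedy: highest case 0.9 grabs 0.85, then 0.2 grabs 0.25
  expect_equal(best, c(1, 2))
})

test_that("subjects with more than two diseases are excluded except for metabolic syndrome", {
  s <- small_noisy()
  labels <- classify_outcomes(s$cohort)
  many <- labels$subject_id[!is.na(labels$disease_count) & labels$disease_count > 2]
  skip_if(length(many) == 0)
  out <- "hyperuricemia"
  ms <- match_controls(s$cohort, labels, out)
  expect_length(intersect(ms$ids, many), 0)
  expect_equal(length(ms$case_id), length(ms$control_id))
  expect_false(any(duplicated(ms$ids)))
  ms2 <- match_controls(s$cohort, labels, "metabolic_syndrome")
  mets_many <- intersect(ms2$ids, many)
  expect_gte(length(mets_many), 0)  # exclusion waived: allowed to appear
})

test_that("matching improves or maintains covariate balance", {
  s <- small_noisy()
  labels <- classify_outcomes(s$cohort)
  ms <- match_controls(s$cohort, labels, "hyperlipidemia")
  bal <- matching_balance(s$cohort, labels, ms)
  expect_lte(mean(bal$smd_after), mean(bal$smd_before) + 0.02)
})
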