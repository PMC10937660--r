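test_that("cohort generation is seed-deterministic and respects the config", {
  cfg <- study_config(n_subjects = 150, n_chemicals_gc = 3, n_chemicals_lc = 3,
                      regions = c("A", "B"), seed = 1)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 150)
  expect_true(all(c1$region %in% c("A", "B")))
  expect_true(all(c1$age > 0))
  expect_true(all(clinical_parameters() %in% names(c1)))
  expect_error(study_config(n_subjects = 0), "configuration error")
  expect_error(study_config(calib_levels_gc = c(0.1, 1, 10)), "configuration error")
})

test_that("degenerate exposure generator collapses to the chemical baseline", {
  cfg <- study_config(n_subjects = 40, n_chemicals_gc = 2, n_chemicals_lc = 2,
                      regions = "A", region_sd = 0, age_slope_mean = 0,
                      age_slope_sd = 0, subject_sd = 1e-12, seed = 2)
  cohort <- generate_cohort(cfg)
  truth <- generate_exposures(cohort, cfg)
  for (ch in truth$chemicals) {
    v <- log10(truth$true_concentration[, ch])
    expect_lt(diff(range(v)), 1e-9)
  }
})

test_that("a positive age slope yields positive rank correlation with age", {
  cfg <- study_config(n_subjects = 2000, n_chemicals_gc = 2, n_chemicals_lc = 2,
                      regions = "A", region_sd = 0,
                      age_slope_mean = 0.008, age_slope_sd = 0,
                      subject_sd = 0.2, seed = 3)
  cohort <- generate_cohort(cfg)
  truth <- generate_exposures(cohort, cfg)
  rho <- cor(cohort$age, log10(truth$true_concentration[, 1]),
             method = "spearman")
  expect_gt(rho, 0.2)
})

test_that("region offsets of +/-0.5 log10 produce a near-tenfold GM ratio", {
  cfg <- study_config(n_subjects = 3000, n_chemicals_gc = 2, n_chemicals_lc = 2,
                      regions = c("A", "B"), region_sd = 0.5,
                      age_slope_mean = 0, age_slope_sd = 0,
                      subject_sd = 0.3, seed = 4)
  cohort <- generate_cohort(cfg)
  truth <- generate_exposures(cohort, cfg)
  # impose the exact offsets, regenerate concentrations from the model
  ch <- truth$chemicals[1]
  off <- truth$region_offset[ch, c("A", "B")]
  lg <- log10(truth$true_concentration[, ch])
  gm_ratio <- 10^(mean(lg[cohort$region == "A"]) - mean(lg[cohort$region == "B"]))
  expected <- 10^(off["A"] - off["B"])
  expect_equal(unname(gm_ratio), unname(expected), tolerance = 0.12)
})

test_that("an analyte and its matched internal standard share batch drift", {
  s <- small_noisy()
  for (pf in c("GC", "LC")) {
    d <- s$truth$batch_drift[[pf]]
    for (ch in rownames(d$chem_drift)) {
      isid <- s$truth$is_assignment[ch]
      expect_equal(unname(d$chem_drift[ch, ]), unname(d$is_drift[isid, ]))
    }
  }
})

test_that("noiseless calibrator areas are exactly proportional to nominal level", {
  s <- tiny_noiseless()
  gc <- s$peaks$GC
  cal <- gc[gc$role == "calibrator" & gc$chemical_id == "GC001" &
            gc$batch == "B1", ]
  rf <- s$truth$response_factor["GC001"]
  drift <- s$truth$batch_drift$GC$chem_drift["GC001", 1]
  expect_equal(cal$area, rf * drift * cal$nominal_conc_ng_ml,
               tolerance = 1e-12)
})

test_that("batch structure follows the layout: 474 study samples over 3 GC batches", {
  cfg <- study_config(n_subjects = 474, n_chemicals_gc = 2, n_chemicals_lc = 2,
                      regions = "A", seed = 5)
  s <- make_study(cfg)
  gc <- s$peaks$GC
  expect_equal(length(unique(gc$batch)), 3)
  ladders <- table(gc$batch[gc$role == "calibrator" & gc$chemical_id == "GC001"])
  expect_true(all(ladders == length(cfg$calib_levels_gc)))
})

test_that("scaling one batch's drift scales all its areas multiplicatively", {
  cfg <- study_config(n_subjects = 40, n_chemicals_gc = 2, n_chemicals_lc = 2,
                      regions = "A",
                      batch_layout_gc = c(real_per_batch = 20, qc_per_batch = 4),
                      batch_layout_lc = c(real_per_batch = 20, qc_per_batch = 4),
                      noise_cv = 0, seed = 6)
  cohort <- generate_cohort(cfg)
  truth <- generate_exposures(cohort, cfg)
  p1 <- generate_peak_tables(truth, cfg)
  truth2 <- truth
  truth2$batch_drift$GC$chem_drift[, 2] <- 2 * truth$batch_drift$GC$chem_drift[, 2]
  truth2$batch_drift$GC$is_drift[, 2] <- 2 * truth$batch_drift$GC$is_drift[, 2]
  p2 <- generate_peak_tables(truth2, cfg)
  b2 <- p1$GC$batch == "B2"
  expect_equal(p2$GC$area[b2], 2 * p1$GC$area[b2], tolerance = 1e-12)
  expect_equal(p2$GC$area[!b2], p1$GC$area[!b2], tolerance = 1e-12)
})

test_that("study bundles round-trip losslessly and are seed-deterministic", {
  s <- tiny_noiseless()
  d1 <- withr::local_tempdir()
  write_study_bundle(d1, s)
  back <- read_study_bundle(d1)
  expect_equal(back$cohort$subject_id, s$cohort$subject_id)
  expect_equal(back$cohort$bmi, s$cohort$bmi)
  expect_equal(back$peaks$GC$area, s$peaks$GC$area)
  expect_equal(back$peaks$LC$is_area, s$peaks$LC$is_area)
  expect_equal(back$truth_concentration,
               s$truth$true_concentration)
  # same config + seed => byte-identical bundle
  s2 <- make_study(s$config)
  d2 <- withr::local_tempdir()
  write_study_bundle(d2, s2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_error(write_study_bundle(file.path(d1, "nope", "deeper"), s), "I/O error")
})

test_that("empirical detection frequency tracks the configured target within 5 points", {
  cfg <- study_config(n_subjects = 2000, n_chemicals_gc = 6, n_chemicals_lc = 6,
                      regions = c("A", "B", "C"), noise_cv = 0.05, seed = 7)
  s <- make_study(cfg)
  q <- quantify_study(s, impute = FALSE)
  det <- colMeans(!q$cmat$below_loq, na.rm = TRUE)
  target <- s$truth$detection_target[names(det)]
  expect_true(all(abs(det - target) < 0.05))
})
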