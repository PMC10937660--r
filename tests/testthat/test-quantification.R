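test_that("calibration fit reproduces exact linear and affine data", {
  f1 <- fit_calibration(c(0.1, 1, 5, 10, 100), c(0.05, 0.5, 2.5, 5, 50))
  expect_equal(f1$slope, 0.5, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  expect_equal(f1$r2, 1, tolerance = 1e-12)

  x <- c(0.5, 1, 2, 5, 10)
  f2 <- fit_calibration(x, 2 * x + 1)
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 1, tolerance = 1e-12)
})

test_that("calibration fit equals the closed-form weighted normal equations", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(6:13, 1)
    x <- sort(10^runif(n, -2, 2))
    y <- 0.3 + 0.8 * x + rnorm(n, 0, 0.05 * x)  # noise proportional to x
    fit <- fit_calibration(x, y)
    oracle <- wls_oracle(x, y, 1 / x)
    expect_equal(fit$intercept, oracle[1], tolerance = 1e-9)
    expect_equal(fit$slope, oracle[2], tolerance = 1e-9)
  }
})

test_that("too few calibrator levels flag the fit unquantifiable", {
  f <- fit_calibration(c(1, 2, 5, 10), c(1, 2, 5, 10))
  expect_false(f$ok)
  expect_equal(f$n_levels, 4)
  expect_error(fit_calibration(rep(2, 6), rnorm(6)), "singular")
})

test_that("the zero-concentration calibrator is excluded from the weighted fit", {
  x <- c(0, 0.5, 1, 2, 5, 10)
  y <- c(99, 2 * c(0.5, 1, 2, 5, 10))  # wild blank cannot influence the fit
  f <- fit_calibration(x, y)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
})

test_that("LOQ is the lowest rung with signal-to-noise strictly above 10", {
  conc <- c(0.02, 0.05, 0.1, 0.2)
  area <- c(5, 25, 60, 105)
  expect_equal(estimate_loq(conc, area, noise_sd = 10), 0.2)
  expect_equal(estimate_loq(conc, area, noise_sd = 1e-9), 0.02)
  expect_equal(estimate_loq(conc, area, noise_sd = 1e6), Inf)
  # boundary: S/N exactly 10 does not qualify
  expect_equal(estimate_loq(c(1, 2), c(100, 101), noise_sd = 10), 2)
  expect_error(estimate_loq(numeric(0), numeric(0), 1), "empty")
})

test_that("retention-time selection picks the nearest candidate", {
  sel <- select_internal_standard("X", c("a", "b"), "gc_rt", rt = 11.2,
                                  candidate_rt = c(a = 5, b = 12))
  expect_equal(sel, "b")
  # tie goes to the earlier-eluting standard
  sel2 <- select_internal_standard("X", c("late", "early"), "gc_rt", rt = 10,
                                   candidate_rt = c(late = 12, early = 8))
  expect_equal(sel2, "early")
  expect_warning(sel3 <- select_internal_standard("X", character(0), "gc_rt"),
                 "external standard")
  expect_equal(sel3, "external")
})


test_that("minimum-RSD selection finds the drift-sharing internal standard", {
  # noiseless: shared drift cancels exactly, RSD_A = 0 < RSD_B
  pt <- build_is_table(drift_a = c(1, 2), drift_b = c(1, 1),
                       drift_analyte = c(1, 2))
  sel <- select_internal_standard("X", c("B", "A"), "lc_min_rsd", peaks = pt)
  expect_equal(sel, "A")
  qa <- serumexposome:::quantify_qcs_one("X", "A", pt, pooled = TRUE)
  expect_equal(sd(qa$measured / qa$nominal), 0, tolerance = 1e-12)
})

test_that("minimum-RSD selection matches a brute-force RSD table on noisy data", {
  for (seed in 1:20) {
    pt <- build_is_table(drift_a = c(1, 1.8, 0.7), drift_b = c(1, 1, 1),
                         drift_analyte = c(1, 1.8, 0.7),
                         noise_cv = 0.05, seed = seed)
    sel <- select_internal_standard("X", c("B", "A"), "lc_min_rsd", peaks = pt)
    # independent oracle: recompute RSDs exhaustively
    rsds <- sapply(c("B", "A"), function(cand) {
      m <- serumexposome:::quantify_qcs_one("X", cand, pt, pooled = TRUE)
      r <- m$measured / m$nominal
      100 * sd(r) / mean(r)
    })
    expect_equal(sel, names(rsds)[which.min(rsds)])
    expect_equal(sel, "A")
  }
})

test_that("quantification inverts the calibration of the sample's own batch", {
  fits <- data.frame(chemical_id = "X", batch = c("B1", "B2"),
                     platform = "LC", slope = c(0.5, 0.25), intercept = 0,
                     r2 = 1, loq = 0.01, is_id = NA, ok = TRUE,
                     stringsAsFactors = FALSE)
  peaks <- data.frame(
    sample_id = c("S1", "S2"), role = "study", batch = c("B1", "B2"),
    platform = "LC", chemical_id = "X", area = 1.0, is_id = NA,
    is_area = NA, nominal_conc_ng_ml = NA, stringsAsFactors = FALSE)
  cm <- quantify_samples(peaks, fits)
  expect_equal(unname(cm$conc["S1", "X"]), 2.0)
  expect_equal(unname(cm$conc["S2", "X"]), 4.0)
})

test_that("noiseless synthetic study is recovered to near machine precision", {
  s <- tiny_noiseless()
  q <- quantify_study(s, impute = FALSE)
  truth <- s$truth$true_concentration[rownames(q$cmat$conc), colnames(q$cmat$conc)]
  rel <- abs(q$cmat$conc - truth) / truth
  expect_lt(max(rel[!q$cmat$below_loq], na.rm = TRUE), 1e-8)
})

test_that("below-LOQ cells are imputed to LOQ/sqrt(2), flags preserved", {
  s <- tiny_noiseless()
  q <- quantify_study(s, impute = FALSE)
  cm <- q$cmat
  imp <- impute_below_loq(cm)
  expect_identical(imp$below_loq, cm$below_loq)
  key <- paste(q$fits$chemical_id, q$fits$batch)
  for (ch in colnames(cm$conc)) {
    idx <- which(cm$below_loq[, ch])
    for (i in idx) {
      loq <- q$fits$loq[match(paste(ch, cm$batch[i, ch]), key)]
      expect_equal(unname(imp$conc[i, ch]), loq / sqrt(2), tolerance = 1e-15)
    }
    above <- which(!cm$below_loq[, ch])
    expect_equal(imp$conc[above, ch], cm$conc[above, ch])
  }
})

test_that("internal-standard correction is immune to whole-batch drift, external mode is not", {
  s <- tiny_noiseless()
  q0 <- quantify_study(s, impute = FALSE)
  # multiply every area (analytes and standards) of GC batch B2 by k
  s2 <- s
  k <- 3.7
  b2 <- s2$peaks$GC$batch == "B2"
  s2$peaks$GC$area[b2] <- k * s2$peaks$GC$area[b2]
  s2$peaks$GC$is_area[b2] <- k * s2$peaks$GC$is_area[b2]
  q1 <- quantify_study(s2, impute = FALSE)
  gc_chems <- s$panel$chemical_id[s$panel$platform == "GC"]
  expect_equal(q1$cmat$conc[, gc_chems], q0$cmat$conc[, gc_chems],
               tolerance = 1e-10)
  # external-standard mode: same perturbation shifts concentrations
  ext <- stats::setNames(rep("external", length(gc_chems)), gc_chems)
  noise <- stats::setNames(s$panel$noise_sd_area, s$panel$chemical_id)
  f0 <- calibrate_study(s$peaks["GC"], noise[gc_chems], is_assignment = ext)
  c0 <- quantify_samples(s$peaks["GC"], f0)
  # drift arising after the batch's calibration run: study-sample signal
  # scales but the curve does not; external mode must move
  s3 <- s
  st_b2 <- s3$peaks$GC$batch == "B2" & s3$peaks$GC$role == "study"
  s3$peaks$GC$area[st_b2] <- k * s3$peaks$GC$area[st_b2]
  f3 <- calibrate_study(s3$peaks["GC"], noise[gc_chems], is_assignment = ext)
  c3 <- quantify_samples(s3$peaks["GC"], f3)
  moved <- abs(c3$conc - c0$conc) / c0$conc
  expect_gt(max(moved, na.rm = TRUE), 1)
})

test_that("raising a study sample's analyte area never lowers its concentration", {
  fits <- data.frame(chemical_id = "X", batch = "B1", platform = "LC",
                     slope = 0.4, intercept = 0.05, r2 = 1, loq = 0.01,
                     is_id = NA, ok = TRUE, stringsAsFactors = FALSE)
  areas <- seq(0.1, 5, length.out = 30)
  peaks <- data.frame(
    sample_id = sprintf("S%02d", seq_along(areas)), role = "study",
    batch = "B1", platform = "LC", chemical_id = "X", area = areas,
    is_id = NA, is_area = NA, nominal_conc_ng_ml = NA,
    stringsAsFactors = FALSE)
  cm <- quantify_samples(peaks, fits)
  expect_true(all(diff(cm$conc[, "X"]) >= 0))
})

test_that("curve accuracy is measured/nominal with an 80-120 percent band", {
  s <- tiny_noiseless()
  q <- quantify_study(s, impute = FALSE)
  acc <- evaluate_curve_accuracy(q$fits, s$peaks)
  expect_true(all(abs(acc$accuracy_pct[!is.na(acc$accuracy_pct)] - 100) < 1e-6))
  expect_true(all(acc$pass[!is.na(acc$pass)]))
})
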