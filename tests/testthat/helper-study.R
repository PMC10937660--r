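# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small noiseless study: 60 subjects, 4+4 chemicals, 3 GC batches.
tiny_noiseless <- function() fixture("tiny_noiseless", {
  cfg <- study_config(n_subjects = 60, n_chemicals_gc = 4, n_chemicals_lc = 4,
                      regions = c("A", "B"),
                      batch_layout_gc = c(real_per_batch = 20, qc_per_batch = 6),
                      batch_layout_lc = c(real_per_batch = 30, qc_per_batch = 6),
                      noise_cv = 0, seed = 42)
  make_study(cfg)
})

# Moderate noisy study reused by several modules.
small_noisy <- function() fixture("small_noisy", {
  cfg <- study_config(n_subjects = 400, n_chemicals_gc = 5, n_chemicals_lc = 5,
                      regions = c("A", "B", "C"),
                      batch_layout_gc = c(real_per_batch = 100, qc_per_batch = 9),
                      batch_layout_lc = c(real_per_batch = 150, qc_per_batch = 9),
                      noise_cv = 0.05, seed = 99)
  make_study(cfg)
})

quantify_study <- function(study, impute = TRUE, is_assignment = NULL) {
  noise <- stats::setNames(study$panel$noise_sd_area, study$panel$chemical_id)
  isa <- is_assignment %||% study$truth$is_assignment
  fits <- calibrate_study(study$peaks, noise, is_assignment = isa)
  cm <- quantify_samples(study$peaks, fits)
  if (impute) cm <- impute_below_loq(cm)
  list(fits = fits, cmat = cm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form weighted least squares (normal equations), the independent
# oracle for calibration fits.
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  unname(drop(b))
}

# A cohort with fully controlled clinical values for classifier tests.
boundary_cohort <- function(rows) {
  defaults <- list(sex = "M", age = 50, region = "A", sampling_month = "Aug",
                   education = "primary", income = 10000,
                   marital_status = "married", smoking = "no", drinking = "no",
                   uric_acid = 200, hba1c = 5, ldl_c = 2, triglycerides = 1,
                   total_cholesterol = 4, sbp = 110, dbp = 70, waistline = 70,
                   bmi = 22)
  out <- lapply(seq_along(rows), function(i) {
    r <- utils::modifyList(defaults, rows[[i]])
    r$subject_id <- sprintf("P%03d", i)
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  class(df) <- c("cohort_table", "data.frame")
  df
}

# Hand-built two-candidate peak table: candidate A shares the analyte's
# drift, candidate B does not.
build_is_table <- function(drift_a, drift_b, drift_analyte, noise_cv = 0,
                           seed = 1) {
  set.seed(seed)
  ladder <- c(0.1, 0.5, 1, 5, 10, 50)
  rows <- list()
  nz <- function(n) 1 + rnorm(n, 0, noise_cv)
  for (b in seq_along(drift_analyte)) {
    bid <- paste0("B", b)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("%s_CAL%02d", bid, seq_along(ladder)),
      role = "calibrator", batch = bid, platform = "LC", chemical_id = "X",
      area = 100 * ladder * drift_analyte[b] * nz(length(ladder)),
      is_id = "A", is_area = NA, nominal_conc_ng_ml = ladder)
    for (qi in 1:4) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s_QC%02d", bid, qi), role = "qc", batch = bid,
        platform = "LC", chemical_id = "X",
        area = 100 * 2 * drift_analyte[b] * nz(1),
        is_id = "A", is_area = NA, nominal_conc_ng_ml = 2)
    }
    for (cand in c("A", "B")) {
      d <- if (cand == "A") drift_a[b] else drift_b[b]
      ids <- c(sprintf("%s_CAL%02d", bid, seq_along(ladder)),
               sprintf("%s_QC%02d", bid, 1:4))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids, role = c(rep("calibrator", length(ladder)), rep("qc", 4)),
        batch = bid, platform = "LC", chemical_id = cand,
        area = 5000 * d * nz(length(ids)),
        is_id = NA, is_area = NA,
        nominal_conc_ng_ml = c(ladder, rep(2, 4)))
    }
  }
  do.call(rbind, rows)
}
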