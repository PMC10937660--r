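#' Study configuration for the synthetic biomonitoring cohort
#'
#' Bundles every knob of the synthetic-study generator: cohort size, panel
#' sizes for the two virtual platforms ("GC" and "LC"), region labels, batch
#' layouts, calibration ladders, QC spike levels and the error-model
#' parameters. Defaults emulate a large multi-province serum biomonitoring
#' campaign: 5696 subjects from 15 regions, 97 GC and 170 LC chemicals,
#' GC batches of 158 real + 21 QC samples and LC batches of 264 real + 24 QC
#' samples, GC calibration at 0--100 ng/mL over 13 levels and LC calibration
#' at 0--200 ng/mL over 18 levels.
#'
#' @param n_subjects number of study subjects.
#' @param n_chemicals_gc,n_chemicals_lc panel sizes per platform.
#' @param regions character vector of region labels.
#' @param batch_layout_gc,batch_layout_lc named numeric vectors with
#'   `real_per_batch` and `qc_per_batch`.
#' @param calib_levels_gc,calib_levels_lc calibration ladders in ng/mL,
#'   strictly increasing and starting at 0.
#' @param qc_spike_levels_gc,qc_spike_levels_lc QC spike concentrations in
#'   ng/mL; interleaved QC injections cycle through these levels so both
#'   precision (RSD) and per-level accuracy can be evaluated.
#' @param noise_cv multiplicative area noise, as a coefficient of variation
#'   (0.05 = 5\% area CV). Gaussian, truncated at -0.99 so areas stay
#'   positive.
#' @param drift_sd log-normal standard deviation (natural-log scale) of the
#'   per-batch multiplicative instrument drift.
#' @param region_sd standard deviation (log10 ng/mL) of per-chemical region
#'   offsets.
#' @param age_slope_mean,age_slope_sd distribution of the per-chemical age
#'   slope, in log10 ng/mL per year.
#' @param subject_sd residual between-subject standard deviation, log10
#'   ng/mL.
#' @param detection_range range the per-chemical target detection
#'   frequencies are drawn from (fractions).
#' @param n_outcome_active,outcome_log_or_range number of chemicals with a
#'   non-zero default effect on the simulated binary outcome and the range
#'   their log odds ratios (per log10 ng/mL) are drawn from.
#' @param missing_rate fraction of clinical values set missing (default 0:
#'   complete data).
#' @param seed integer seed; fully determines every generated table.
#' @return a `study_config` list, validated.
#' @export
study_config <- function(n_subjects = 5696,
                         n_chemicals_gc = 97,
                         n_chemicals_lc = 170,
                         regions = sprintf("R%02d", 1:15),
                         batch_layout_gc = c(real_per_batch = 158, qc_per_batch = 21),
                         batch_layout_lc = c(real_per_batch = 264, qc_per_batch = 24),
                         calib_levels_gc = c(0, 0.02, 0.05, 0.1, 0.2, 0.5, 1,
                                             2, 5, 10, 20, 50, 100),
                         calib_levels_lc = c(0, 0.001, 0.0025, 0.005, 0.01,
                                             0.025, 0.05, 0.1, 0.25, 0.5, 1,
                                             2.5, 5, 10, 25, 50, 100, 200),
                         qc_spike_levels_gc = c(2, 5, 20),
                         qc_spike_levels_lc = c(1, 10, 100),
                         noise_cv = 0.05,
                         drift_sd = 0.25,
                         region_sd = 0.3,
                         age_slope_mean = 0.004,
                         age_slope_sd = 0.003,
                         subject_sd = 0.4,
                         detection_range = c(0.15, 1),
                         n_outcome_active = 5,
                         outcome_log_or_range = c(0.3, 0.7),
                         missing_rate = 0,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_chemicals_gc = as.integer(n_chemicals_gc),
    n_chemicals_lc = as.integer(n_chemicals_lc),
    regions = as.character(regions),
    batch_layout_gc = batch_layout_gc,
    batch_layout_lc = batch_layout_lc,
    calib_levels_gc = calib_levels_gc,
    calib_levels_lc = calib_levels_lc,
    qc_spike_levels_gc = qc_spike_levels_gc,
    qc_spike_levels_lc = qc_spike_levels_lc,
    noise_cv = noise_cv,
    drift_sd = drift_sd,
    region_sd = region_sd,
    age_slope_mean = age_slope_mean,
    age_slope_sd = age_slope_sd,
    subject_sd = subject_sd,
    detection_range = detection_range,
    n_outcome_active = as.integer(n_outcome_active),
    outcome_log_or_range = outcome_log_or_range,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  counts <- c(cfg$n_subjects, cfg$n_chemicals_gc, cfg$n_chemicals_lc,
              cfg$batch_layout_gc, cfg$batch_layout_lc)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop_input("configuration error: all counts and batch layouts must be > 0")
  for (lv in list(cfg$calib_levels_gc, cfg$calib_levels_lc)) {
    if (lv[1] != 0 || any(diff(lv) <= 0))
      stop_input("configuration error: calibration ladder must start at 0 and be strictly increasing")
  }
  if (length(cfg$regions) < 1) stop_input("configuration error: need >= 1 region")
  if (any(cfg$qc_spike_levels_gc <= 0) || any(cfg$qc_spike_levels_lc <= 0))
    stop_input("configuration error: QC spike levels must be > 0")
  invisible(cfg)
}

#' Small demonstration configuration
#'
#' The default end-to-end bundle used by the pipeline smoke runs: 800
#' subjects, 10 chemicals per platform, 4 regions, with the full-size batch
#' layouts and calibration ladders.
#' @param seed integer seed.
#' @param ... overrides passed to [study_config()].
#' @export
demo_config <- function(seed = 1L, ...) {
  study_config(n_subjects = 800, n_chemicals_gc = 10, n_chemicals_lc = 10,
               regions = sprintf("R%02d", 1:4), seed = seed, ...)
}

# Months assigned per region block: field sampling proceeded region by
# region, so region and sampling month are confounded by design.
region_months <- function(regions) {
  months <- c("Aug", "Sep", "Oct", "Nov")
  stats::setNames(months[((seq_along(regions) - 1) %% 4) + 1], regions)
}

#' Generate the epidemiological cohort table
#'
#' One row per subject with the 9 epidemiological factors (sex, age, region,
#' sampling month, education, income, marital status, smoking, drinking) and
#' the 9 clinical chronic-disease parameters, drawn from distributions
#' centred near the marginals of a large Chinese chronic-disease cohort
#' (e.g. age 51 +/- 17 y, BMI 23.9 +/- 3.8 kg/m2, sex-specific uric acid and
#' waistline).
#'
#' @param config a [study_config()].
#' @return a data.frame of class `cohort_table`.
#' @export
generate_cohort <- function(config) {
  validate_study_config(config)
  n <- config$n_subjects
  set.seed(derive_seed(config$seed, 1L))

  subject_id <- sprintf("S%05d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(2607, 3089) / 5696)
  age <- round(rnorm_trunc(n, 51, 17, lo = 20, hi = 90))
  region <- sort(sample(config$regions, n, replace = TRUE))
  sampling_month <- unname(region_months(config$regions)[region])
  education <- sample(c("primary", "junior_high", "high_school", "university"),
                      n, replace = TRUE,
                      prob = c(2108, 1828, 1236, 524) / 5696)
  income <- round(stats::rlnorm(n, meanlog = log(13000), sdlog = 1.0))
  marital_status <- sample(c("married", "unmarried", "other"), n,
                           replace = TRUE, prob = c(4853, 468, 375) / 5696)
  male <- sex == "M"
  smoking <- ifelse(male, sample(c("yes", "no"), n, TRUE, c(0.5, 0.5)),
                    sample(c("yes", "no"), n, TRUE, c(0.02, 0.98)))
  drinking <- ifelse(male, sample(c("yes", "no"), n, TRUE, c(0.55, 0.45)),
                     sample(c("yes", "no"), n, TRUE, c(0.03, 0.97)))

  uric_acid <- ifelse(male, rnorm_trunc(n, 323, 85, lo = 80),
                      rnorm_trunc(n, 265, 74, lo = 80))
  hba1c <- rnorm_trunc(n, 5.7, 0.9, lo = 3.5)
  ldl_c <- rnorm_trunc(n, 3.1, 0.9, lo = 0.3)
  triglycerides <- stats::rlnorm(n, meanlog = log(1.2), sdlog = 0.55)
  total_cholesterol <- rnorm_trunc(n, 4.9, 1.1, lo = 1.5)
  sbp <- rnorm_trunc(n, 127, 20, lo = 70)
  dbp <- rnorm_trunc(n, 81, 12, lo = 40)
  waistline <- ifelse(male, rnorm_trunc(n, 85, 12, lo = 50),
                      rnorm_trunc(n, 82, 11, lo = 50))
  bmi <- rnorm_trunc(n, 23.9, 3.8, lo = 13)

  cohort <- data.frame(
    subject_id, sex, age, region, sampling_month, education, income,
    marital_status, smoking, drinking,
    uric_acid = round(uric_acid, 1), hba1c = round(hba1c, 2),
    ldl_c = round(ldl_c, 2), triglycerides = round(triglycerides, 2),
    total_cholesterol = round(total_cholesterol, 2),
    sbp = round(sbp), dbp = round(dbp),
    waistline = round(waistline, 1), bmi = round(bmi, 1),
    stringsAsFactors = FALSE
  )

  if (config$missing_rate > 0) {
    clin <- clinical_parameters()
    for (p in clin) {
      miss <- stats::runif(n) < config$missing_rate
      cohort[[p]][miss] <- NA
    }
  }
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Names of the 9 clinical chronic-disease parameters
#' @export
clinical_parameters <- function() {
  c("uric_acid", "hba1c", "ldl_c", "triglycerides", "total_cholesterol",
    "sbp", "dbp", "waistline", "bmi")
}

#' Names of the 9 epidemiological factors
#' @export
epi_factors <- function() {
  c("sex", "age", "region", "sampling_month", "education", "income",
    "marital_status", "smoking", "drinking")
}

#' Generate the chemical panel configuration
#'
#' Chemical identities for both platforms with a category, a retention time,
#' the candidate internal standards of the platform, a true internal-standard
#' assignment (for the GC platform the nearest-retention-time standard, for
#' the LC platform a drift-sharing standard the data-driven selection should
#' recover) and guidance values for a subset of chemicals.
#'
#' @param config a [study_config()].
#' @return data.frame: chemical_id, platform, category, rt,
#'   is_candidates (comma-separated), true_is, guidance_type,
#'   guidance_value_ng_ml.
#' @export
generate_panel <- function(config) {
  validate_study_config(config)
  set.seed(derive_seed(config$seed, 2L))
  cats <- c("OCP", "OPP", "PAH", "PCB", "PFAS", "phthalate", "phenol", "other")
  one_platform <- function(platform, n_chem, rt_range) {
    n_is <- max(2L, ceiling(n_chem / 12))
    is_id <- sprintf("%s_IS%02d", platform, seq_len(n_is))
    is_rt <- seq(rt_range[1], rt_range[2], length.out = n_is)
    chem <- data.frame(
      chemical_id = sprintf("%s%03d", platform, seq_len(n_chem)),
      platform = platform,
      category = sample(cats, n_chem, replace = TRUE),
      rt = round(stats::runif(n_chem, rt_range[1], rt_range[2]), 3),
      stringsAsFactors = FALSE
    )
    chem$is_candidates <- paste(is_id, collapse = ",")
    # GC: static nearest-retention-time assignment (ties to the
    # earlier-eluting standard). LC: a randomly chosen drift-sharing partner.
    if (platform == "GC") {
      idx <- vapply(chem$rt, function(r) {
        d <- abs(is_rt - r)
        which(d == min(d))[1]
      }, integer(1))
    } else {
      idx <- sample.int(n_is, n_chem, replace = TRUE)
    }
    chem$true_is <- is_id[idx]
    list(chem = chem,
         is_table = data.frame(is_id = is_id, platform = platform,
                               rt = round(is_rt, 3), stringsAsFactors = FALSE))
  }
  gc <- one_platform("GC", config$n_chemicals_gc, c(5, 30))
  lc <- one_platform("LC", config$n_chemicals_lc, c(0.5, 15))
  panel <- rbind(gc$chem, lc$chem)
  # Guidance values (serum ng/mL) for roughly a fifth of the panel.
  has_gv <- seq_len(nrow(panel)) %% 5 == 0
  panel$guidance_type <- ifelse(has_gv,
                                sample(c("HBM-II", "BE", "BGV", "RfD"),
                                       nrow(panel), replace = TRUE), NA)
  panel$guidance_value_ng_ml <- ifelse(has_gv,
                                       round(10^stats::runif(nrow(panel), 0, 1.5), 2),
                                       NA)
  attr(panel, "is_table") <- rbind(gc$is_table, lc$is_table)
  panel
}

#' Generate true exposure concentrations and the instrument truth record
#'
#' Log10 true concentration of chemical j in subject i is
#' `baseline_j + region_offset_j(region_i) + age_slope_j * (age_i - 50) +
#' eps_ij`, with `eps ~ N(0, subject_sd)`. Region offsets dominate the age
#' trend under the defaults, mirroring a biomonitoring campaign in which
#' region is the leading determinant of exposure level. Each chemical's
#' baseline is solved (by root finding against the realised cohort) so its
#' expected detection frequency -- the fraction of subjects above the
#' chemical's designed limit of quantification -- hits a target drawn from
#' `config$detection_range`.
#'
#' The truth record also fixes the instrument model: per-chemical response
#' factors (area per ng/mL), per-batch multiplicative drift defined at the
#' internal-standard group level (so an analyte and its matched internal
#' standard share drift exactly -- the property internal-standard correction
#' exploits), chromatogram noise floors that set the designed LOQ, and
#' default outcome effects.
#'
#' @param cohort a [generate_cohort()] table.
#' @param config the matching [study_config()].
#' @param panel optional panel from [generate_panel()]; generated if NULL.
#' @return a `synthetic_truth` list.
#' @export
generate_exposures <- function(cohort, config, panel = NULL) {
  if (nrow(cohort) == 0) stop_input("cohort is empty")
  if (is.null(panel)) panel <- generate_panel(config)
  is_table <- attr(panel, "is_table")
  set.seed(derive_seed(config$seed, 3L))

  n <- nrow(cohort)
  chems <- panel$chemical_id
  K <- length(chems)
  regions <- config$regions

  region_offset <- matrix(stats::rnorm(K * length(regions), 0, config$region_sd),
                          nrow = K, dimnames = list(chems, regions))
  age_slope <- stats::setNames(
    stats::rnorm(K, config$age_slope_mean, config$age_slope_sd), chems)
  subject_sd <- stats::setNames(rep(config$subject_sd, K), chems)

  # Instrument model.
  response_factor <- stats::setNames(stats::rlnorm(K, log(1e4), 0.5), chems)
  is_response <- stats::setNames(
    stats::rlnorm(nrow(is_table), log(1e4), 0.3), is_table$is_id)
  # Designed LOQ: a low rung of the platform ladder per chemical; the
  # chromatogram noise floor is set so S/N at that rung is just above 10.
  loq_design <- numeric(K); names(loq_design) <- chems
  for (j in seq_len(K)) {
    ladder <- if (panel$platform[j] == "GC") config$calib_levels_gc else config$calib_levels_lc
    low <- ladder[ladder > 0][1:3]
    loq_design[j] <- sample(low, 1)
  }
  noise_sd_area <- response_factor * loq_design / 10.5

  # Per-batch drift at the internal-standard group level.
  drift <- list()
  for (pf in c("GC", "LC")) {
    layout <- if (pf == "GC") config$batch_layout_gc else config$batch_layout_lc
    n_batch <- ceiling(n / layout[["real_per_batch"]])
    is_ids <- is_table$is_id[is_table$platform == pf]
    is_drift <- matrix(stats::rlnorm(length(is_ids) * n_batch, 0, config$drift_sd),
                       nrow = length(is_ids),
                       dimnames = list(is_ids, paste0("B", seq_len(n_batch))))
    pchem <- panel$chemical_id[panel$platform == pf]
    chem_drift <- is_drift[panel$true_is[match(pchem, panel$chemical_id)], ,
                           drop = FALSE]
    rownames(chem_drift) <- pchem
    drift[[pf]] <- list(is_drift = is_drift, chem_drift = chem_drift,
                        n_batch = n_batch)
  }

  # Detection-frequency targets and baselines. Baselines are solved against
  # the realized per-batch LOQ (the lowest ladder rung whose drift-scaled
  # signal-to-noise exceeds 10 for the subject's own batch), so the
  # empirical detection frequency converges to the configured target.
  target <- stats::setNames(
    stats::runif(K, config$detection_range[1], config$detection_range[2]), chems)
  agec <- cohort$age - 50
  ridx <- match(cohort$region, regions)
  baseline <- numeric(K); names(baseline) <- chems
  for (j in seq_len(K)) {
    pf <- panel$platform[j]
    layout <- if (pf == "GC") config$batch_layout_gc else config$batch_layout_lc
    ladder <- if (pf == "GC") config$calib_levels_gc else config$calib_levels_lc
    rungs <- ladder[ladder > 0]
    subj_batch <- ceiling(seq_len(n) / layout[["real_per_batch"]])
    dj <- drift[[pf]]$chem_drift[chems[j], ]
    # expected batch LOQ: S/N at rung L is rf*L*drift / noise_sd
    sn1 <- response_factor[j] * dj / noise_sd_area[j]  # S/N per unit conc
    loq_batch <- vapply(sn1, function(s) {
      hit <- rungs[s * rungs > 10]
      if (length(hit)) hit[1] else Inf
    }, numeric(1))
    l_subj <- log10(loq_batch[subj_batch])
    shift <- region_offset[j, ridx] + age_slope[j] * agec
    f <- function(b) {
      p <- stats::pnorm((b + shift - l_subj) / subject_sd[j])
      p[!is.finite(l_subj)] <- 0
      mean(p) - target[j]
    }
    lmid <- log10(loq_design[j])
    baseline[j] <- tryCatch(
      stats::uniroot(f, c(lmid - 8 * subject_sd[j] - 6,
                          lmid + 8 * subject_sd[j] + 6))$root,
      error = function(e) lmid)  # target unreachable (all-Inf LOQ)
  }

  log10c <- matrix(stats::rnorm(n * K, 0, 1), n, K) *
    rep(subject_sd, each = n) +
    rep(baseline, each = n) +
    t(region_offset)[ridx, , drop = FALSE] +
    outer(agec, age_slope)
  true_concentration <- 10^log10c
  dimnames(true_concentration) <- list(cohort$subject_id, chems)

  # Default outcome effects: a few active chemicals, modest log odds ratios.
  outcome_effects <- stats::setNames(rep(0, K), chems)
  n_act <- min(config$n_outcome_active, K)
  if (n_act > 0) {
    act <- sample(chems, n_act)
    outcome_effects[act] <- stats::runif(n_act, config$outcome_log_or_range[1],
                                         config$outcome_log_or_range[2])
  }

  truth <- list(
    panel = panel, is_table = is_table, chemicals = chems,
    baseline = baseline, region_offset = region_offset,
    age_slope = age_slope, subject_sd = subject_sd,
    detection_target = target,
    true_concentration = true_concentration,
    response_factor = response_factor, is_response = is_response,
    loq_design = loq_design, noise_sd_area = noise_sd_area,
    batch_drift = drift, is_assignment = stats::setNames(panel$true_is, chems),
    outcome_effects = outcome_effects, noise_cv = config$noise_cv
  )
  class(truth) <- "synthetic_truth"
  truth
}

# Multiplicative Gaussian area noise, truncated at -0.99 so areas stay
# positive.
area_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  pmax(1 + stats::rnorm(n, 0, cv), 0.01)
}

#' Generate long-format peak tables for both platforms
#'
#' Each batch holds a full calibration ladder, interleaved QC spikes cycling
#' through the configured levels, and its study samples. An analyte's area is
#' `response_factor * concentration * batch_drift * (1 + eps)` with
#' multiplicative Gaussian noise; its internal standard's area is
#' `is_response * batch_drift * (1 + eps')` with the same drift factor, which
#' is precisely what the analyte/IS ratio cancels.
#'
#' @param truth a [generate_exposures()] truth record.
#' @param config the matching [study_config()].
#' @return named list of two `peak_table` data.frames (`GC`, `LC`) with
#'   columns sample_id, role, batch, platform, chemical_id, area, is_id,
#'   is_area, nominal_conc_ng_ml. Internal-standard records appear as their
#'   own chemical_id rows with is_id = NA.
#' @export
generate_peak_tables <- function(truth, config) {
  panel <- truth$panel
  if (!all(panel$chemical_id %in% names(truth$response_factor)))
    stop_input("generation error: chemical without response factor")
  set.seed(derive_seed(config$seed, 4L))
  subjects <- rownames(truth$true_concentration)
  n <- length(subjects)
  out <- list()
  for (pf in c("GC", "LC")) {
    layout <- if (pf == "GC") config$batch_layout_gc else config$batch_layout_lc
    ladder <- if (pf == "GC") config$calib_levels_gc else config$calib_levels_lc
    spikes <- if (pf == "GC") config$qc_spike_levels_gc else config$qc_spike_levels_lc
    n_batch <- truth$batch_drift[[pf]]$n_batch
    qc_n <- layout[["qc_per_batch"]]

    samp <- list()
    for (b in seq_len(n_batch)) {
      bid <- paste0("B", b)
      cal <- data.frame(
        sample_id = sprintf("%s_%s_CAL%02d", pf, bid, seq_along(ladder)),
        role = "calibrator", batch = bid,
        nominal_conc_ng_ml = ladder, stringsAsFactors = FALSE)
      qc <- data.frame(
        sample_id = sprintf("%s_%s_QC%02d", pf, bid, seq_len(qc_n)),
        role = "qc", batch = bid,
        nominal_conc_ng_ml = rep_len(spikes, qc_n), stringsAsFactors = FALSE)
      idx <- which(ceiling(seq_len(n) / layout[["real_per_batch"]]) == b)
      st <- data.frame(
        sample_id = subjects[idx], role = "study", batch = bid,
        nominal_conc_ng_ml = NA_real_, stringsAsFactors = FALSE)
      samp[[b]] <- rbind(cal, qc, st)
    }
    samp <- do.call(rbind, samp)

    pchem <- panel$chemical_id[panel$platform == pf]
    chem_drift <- truth$batch_drift[[pf]]$chem_drift
    is_drift <- truth$batch_drift[[pf]]$is_drift
    is_ids <- rownames(is_drift)

    # Analyte rows: samples x chemicals.
    m <- nrow(samp)
    tab <- data.frame(
      sample_id = rep(samp$sample_id, times = length(pchem)),
      role = rep(samp$role, times = length(pchem)),
      batch = rep(samp$batch, times = length(pchem)),
      platform = pf,
      chemical_id = rep(pchem, each = m),
      stringsAsFactors = FALSE)
    conc <- rep(samp$nominal_conc_ng_ml, times = length(pchem))
    study_rows <- tab$role == "study"
    conc[study_rows] <- truth$true_concentration[
      cbind(tab$sample_id[study_rows], tab$chemical_id[study_rows])]
    bnum <- as.integer(sub("^B", "", tab$batch))
    drift_vec <- chem_drift[cbind(match(tab$chemical_id, rownames(chem_drift)), bnum)]
    tab$area <- truth$response_factor[tab$chemical_id] * conc * drift_vec *
      area_noise(nrow(tab), truth$noise_cv)
    tab$is_id <- truth$is_assignment[tab$chemical_id]

    # Internal-standard rows: samples x standards.
    is_tab <- data.frame(
      sample_id = rep(samp$sample_id, times = length(is_ids)),
      role = rep(samp$role, times = length(is_ids)),
      batch = rep(samp$batch, times = length(is_ids)),
      platform = pf,
      chemical_id = rep(is_ids, each = m),
      stringsAsFactors = FALSE)
    ibnum <- as.integer(sub("^B", "", is_tab$batch))
    is_tab$area <- truth$is_response[is_tab$chemical_id] *
      is_drift[cbind(match(is_tab$chemical_id, rownames(is_drift)), ibnum)] *
      area_noise(nrow(is_tab), truth$noise_cv)
    is_tab$is_id <- NA_character_
    is_tab$nominal_conc_ng_ml <- NA_real_

    # Join each analyte row to its standard's area in the same injection.
    key_is <- paste(is_tab$sample_id, is_tab$chemical_id)
    tab$is_area <- is_tab$area[match(paste(tab$sample_id, tab$is_id), key_is)]
    is_tab$is_area <- NA_real_
    tab$nominal_conc_ng_ml <- conc
    tab$nominal_conc_ng_ml[study_rows] <- NA_real_

    cols <- c("sample_id", "role", "batch", "platform", "chemical_id",
              "area", "is_id", "is_area", "nominal_conc_ng_ml")
    res <- rbind(tab[, cols], is_tab[, cols])
    rownames(res) <- NULL
    class(res) <- c("peak_table", "data.frame")
    out[[pf]] <- res
  }
  out
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper: cohort, panel, truth record and peak tables under a
#' single seed.
#' @param config a [study_config()].
#' @return list with `config`, `cohort`, `panel`, `truth`, `peaks`.
#' @export
make_study <- function(config = study_config()) {
  cohort <- generate_cohort(config)
  truth <- generate_exposures(cohort, config)
  peaks <- generate_peak_tables(truth, config)
  panel <- truth$panel
  # chromatogram noise floor per chemical, as a peak-integration report would
  # carry it; needed downstream for LOQ estimation
  panel$noise_sd_area <- unname(truth$noise_sd_area[panel$chemical_id])
  attr(panel, "is_table") <- attr(truth$panel, "is_table")
  list(config = config, cohort = cohort, panel = panel,
       truth = truth, peaks = peaks)
}

#' Simulate a binary disease outcome with a logistic link on true exposure
#'
#' Linear predictor: `a0 + sum_j beta_j * log10(C_ij) + covariate terms`,
#' with the intercept solved so the marginal prevalence matches `prevalence`.
#'
#' @param truth a `synthetic_truth`.
#' @param cohort the cohort table.
#' @param effects named log odds ratios per log10(ng/mL); defaults to the
#'   truth record's `outcome_effects`.
#' @param prevalence target marginal prevalence.
#' @param sex_effect,age_effect optional covariate log odds (male vs female;
#'   per year of age).
#' @param seed integer seed.
#' @return integer 0/1 vector, one per subject.
#' @export
generate_outcome <- function(truth, cohort, effects = NULL, prevalence = 0.3,
                             sex_effect = 0, age_effect = 0, seed = 1L) {
  effects <- effects %||% truth$outcome_effects
  effects <- effects[effects != 0]
  lp <- rep(0, nrow(cohort))
  if (length(effects)) {
    lg <- log10(truth$true_concentration[, names(effects), drop = FALSE])
    lp <- lp + drop(lg %*% effects)
  }
  lp <- lp + sex_effect * (cohort$sex == "M") + age_effect * (cohort$age - 50)
  f <- function(a0) mean(stats::plogis(a0 + lp)) - prevalence
  a0 <- stats::uniroot(f, c(-40, 40))$root
  set.seed(seed)
  as.integer(stats::runif(nrow(cohort)) < stats::plogis(a0 + lp))
}

#' Write a study bundle to plain CSV files
#'
#' Writes cohort, both peak tables, the panel configuration, guidance values
#' and the true concentration record. Numeric columns are written at full
#' (17 significant digit) precision so the bundle round-trips losslessly
#' through [read_study_bundle()].
#'
#' @param dir existing, writable output directory.
#' @param study a [make_study()] bundle.
#' @export
write_study_bundle <- function(dir, study) {
  if (!dir.exists(dir)) stop_input("I/O error: directory '%s' does not exist", dir)
  if (file.access(dir, 2) != 0) stop_input("I/O error: directory '%s' not writable", dir)
  wr <- function(df, name) {
    df2 <- df
    for (cl in names(df2)) {
      if (is.numeric(df2[[cl]]))
        df2[[cl]] <- ifelse(is.na(df2[[cl]]), NA, sprintf("%.17g", df2[[cl]]))
    }
    utils::write.csv(df2, file.path(dir, name), row.names = FALSE, quote = TRUE)
  }
  wr(as.data.frame(study$cohort), "cohort.csv")
  wr(as.data.frame(study$peaks$GC), "peaks_gc.csv")
  wr(as.data.frame(study$peaks$LC), "peaks_lc.csv")
  panel <- study$panel
  wr(as.data.frame(panel), "panel.csv")
  wr(attr(panel, "is_table"), "internal_standards.csv")
  gv <- panel[!is.na(panel$guidance_value_ng_ml),
              c("chemical_id", "guidance_type", "guidance_value_ng_ml")]
  names(gv) <- c("chemical_id", "type", "value_ng_ml")
  wr(gv, "guidance.csv")
  tc <- as.data.frame(study$truth$true_concentration)
  tc <- cbind(subject_id = rownames(study$truth$true_concentration), tc)
  wr(tc, "truth_concentrations.csv")
  invisible(file.path(dir, c("cohort.csv", "peaks_gc.csv", "peaks_lc.csv",
                             "panel.csv", "internal_standards.csv",
                             "guidance.csv", "truth_concentrations.csv")))
}

#' Read a study bundle written by [write_study_bundle()]
#' @param dir bundle directory.
#' @return list with `cohort`, `peaks` (GC/LC), `panel`, `guidance`,
#'   `truth_concentration` matrix.
#' @export
read_study_bundle <- function(dir) {
  rd <- function(name) utils::read.csv(file.path(dir, name),
                                       stringsAsFactors = FALSE)
  cohort <- rd("cohort.csv")
  class(cohort) <- c("cohort_table", "data.frame")
  peaks <- list(GC = rd("peaks_gc.csv"), LC = rd("peaks_lc.csv"))
  for (pf in names(peaks)) class(peaks[[pf]]) <- c("peak_table", "data.frame")
  panel <- rd("panel.csv")
  attr(panel, "is_table") <- rd("internal_standards.csv")
  tc <- rd("truth_concentrations.csv")
  m <- as.matrix(tc[, -1, drop = FALSE])
  rownames(m) <- tc$subject_id
  list(cohort = cohort, peaks = peaks, panel = panel,
       guidance = rd("guidance.csv"), truth_concentration = m)
}
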