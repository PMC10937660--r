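#' Pipeline configuration
#'
#' Options for [run_pipeline()]: where to read or simulate the study, which
#' stages to run and the model options that matter (bootstrap count, spline
#' knots, association outcome, how many chemicals to model singly).
#'
#' @param out output directory (created if missing).
#' @param study a [study_config()] used when `simulate = TRUE`; default
#'   [demo_config()].
#' @param simulate generate the study bundle (TRUE) or read one from
#'   `input_dir` (FALSE).
#' @param input_dir bundle directory when `simulate = FALSE`.
#' @param seed global seed; propagates to every stochastic stage.
#' @param outcome outcome for the association, mixture and dose-risk stages.
#' @param n_assoc_chemicals how many high-frequency chemicals get single-
#'   exposure models.
#' @param n_boot WQS bootstrap count for the pipeline run.
#' @param n_knots dose-risk spline knots.
#' @param stages character vector of stages to run, in canonical order.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out,
                            study = demo_config(seed = seed),
                            simulate = TRUE,
                            input_dir = NULL,
                            seed = 1L,
                            outcome = "hyperlipidemia",
                            n_assoc_chemicals = 5L,
                            n_boot = 20L,
                            n_knots = 4L,
                            stages = c("simulate", "quantify", "qc",
                                       "outcomes", "characterize", "assoc",
                                       "mixture", "risk")) {
  cfg <- list(out = out, study = study, simulate = simulate,
              input_dir = input_dir, seed = as.integer(seed),
              outcome = outcome, n_assoc_chemicals = n_assoc_chemicals,
              n_boot = n_boot, n_knots = n_knots, stages = stages)
  class(cfg) <- "pipeline_config"
  if (!simulate) {
    if (is.null(input_dir))
      stop_input("validation error: simulate is disabled and no input_dir is set")
    need <- file.path(input_dir, c("cohort.csv", "peaks_gc.csv", "peaks_lc.csv",
                                   "panel.csv"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop_input("validation error: missing input file(s): %s",
                 paste(basename(miss), collapse = ", "))
  }
  cfg
}

write_stage_csv <- function(df, out, name) {
  path <- file.path(out, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full biomonitoring analysis pipeline
#'
#' Executes simulate (optional), quantify, qc, outcomes, characterize,
#' assoc, mixture and risk in order, writing each stage's tables as CSV
#' under `config$out` plus a machine-readable `manifest.json` (package and R
#' versions, seed, md5 of every output). Reruns with the same configuration
#' and seed reproduce identical outputs. A stage failure aborts with the
#' stage name; earlier outputs are preserved.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly, plus a `results` list of in-memory
#'   objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  results <- list()
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- simulate -------------------------------------------------------
  if ("simulate" %in% config$stages && config$simulate) {
    study <- stage("simulate", {
      s <- make_study(config$study)
      bdir <- file.path(out, "bundle")
      dir.create(bdir, showWarnings = FALSE)
      write_study_bundle(bdir, s)
      s
    })
    files <- c(files, list.files(file.path(out, "bundle"), full.names = TRUE))
  } else {
    if (is.null(config$input_dir))
      stop_input("validation error: simulate is disabled and no input_dir is set")
    b <- read_study_bundle(config$input_dir)
    study <- list(cohort = b$cohort, peaks = b$peaks, panel = b$panel,
                  truth = NULL, config = config$study)
  }
  results$study <- study
  panel <- study$panel
  noise_sd <- stats::setNames(panel$noise_sd_area, panel$chemical_id)

  # --- quantify -------------------------------------------------------
  cmat <- stage("quantify", {
    isa <- assign_internal_standards(panel, study$peaks, noise_sd)
    fits <- calibrate_study(study$peaks, noise_sd, is_assignment = isa)
    cm <- impute_below_loq(quantify_samples(study$peaks, fits))
    files <- c(files,
      write_stage_csv(fits, out, "calibration_report.csv"),
      write_stage_csv(data.frame(subject_id = rownames(cm$conc), cm$conc,
                                 check.names = FALSE), out,
                      "concentrations.csv"),
      write_stage_csv(data.frame(subject_id = rownames(cm$below_loq),
                                 cm$below_loq, check.names = FALSE), out,
                      "below_loq_flags.csv"))
    results$fits <- fits
    cm
  })
  results$cmat <- cmat

  # --- qc -------------------------------------------------------------
  stage("qc", {
    qcs <- quantify_qcs(study$peaks, results$fits)
    rep <- qc_metrics(qcs)
    # before: log10 raw area / nominal (uncorrected signal); after: log10
    # measured / nominal (batch-specific calibration + IS correction).
    # Assessed per platform (QC injections and chemicals do not overlap
    # across platforms), then averaged.
    be_list <- lapply(study$peaks, function(p) {
      qc_rows <- p[p$role == "qc" & p$chemical_id %in% colnames(cmat$conc),
                   c("sample_id", "chemical_id", "batch", "area",
                     "nominal_conc_ng_ml")]
      if (nrow(qc_rows) == 0) return(NULL)
      qm <- qcs[qcs$sample_id %in% qc_rows$sample_id, , drop = FALSE]
      before <- stats::xtabs(log10(area / nominal_conc_ng_ml) ~
                               sample_id + chemical_id, data = qc_rows)
      after <- stats::xtabs(log10(pmax(measured, 1e-12) / nominal) ~
                              sample_id + chemical_id, data = qm)
      common <- intersect(rownames(before), rownames(after))
      cols <- intersect(colnames(before), colnames(after))
      batch <- qc_rows$batch[match(common, qc_rows$sample_id)]
      batch_effect_assessment(before[common, cols, drop = FALSE],
                              after[common, cols, drop = FALSE], batch)
    })
    be_list <- be_list[!vapply(be_list, is.null, logical(1))]
    be <- list(
      metric_before = mean(vapply(be_list, `[[`, numeric(1), "metric_before"),
                           na.rm = TRUE),
      metric_after = mean(vapply(be_list, `[[`, numeric(1), "metric_after"),
                          na.rm = TRUE),
      pca_scores = be_list[[1]]$pca_scores,
      explained = be_list[[1]]$explained)
    files <- c(files,
      write_stage_csv(rep$precision, out, "qc_precision.csv"),
      write_stage_csv(rep$recovery, out, "qc_recovery.csv"),
      write_stage_csv(data.frame(metric_before = be$metric_before,
                                 metric_after = be$metric_after), out,
                      "batch_effect.csv"))
    if (!is.null(be$pca_scores))
      files <- c(files, write_stage_csv(
        be$pca_scores[, seq_len(min(5, ncol(be$pca_scores)))], out,
        "qc_pca_scores.csv"))
    results$qc <- list(report = rep, batch_effect = be)
  })

  # --- outcomes -------------------------------------------------------
  labels <- stage("outcomes", {
    lab <- classify_outcomes(study$cohort)
    files <- c(files, write_stage_csv(as.data.frame(lab), out,
                                       "outcome_labels.csv"))
    lab
  })
  results$labels <- labels

  # --- characterize ---------------------------------------------------
  stage("characterize", {
    summ <- exposure_summary(cmat, study$cohort$region)
    hf <- select_high_frequency(summ)
    lg <- log10(cmat$conc)
    ok_cols <- colnames(lg)[apply(lg, 2, function(v) all(is.finite(v)))]
    fac <- study$cohort[, c("region", "age", "sex", "sampling_month")]
    vp <- variance_partition(lg[, ok_cols, drop = FALSE], fac)
    pca <- pca_scores(lg[, ok_cols, drop = FALSE])
    sd_sex <- stratified_differences(cmat, study$cohort$sex)
    ps_age <- partial_spearman(cmat, study$cohort$age,
                               confounders = study$cohort[, c("sex", "region")])
    files <- c(files,
      write_stage_csv(summ, out, "exposure_summary.csv"),
      write_stage_csv(data.frame(chemical_id = hf), out, "high_frequency.csv"),
      write_stage_csv(vp$per_factor, out, "variance_partition.csv"),
      write_stage_csv(sd_sex, out, "differences_by_sex.csv"),
      write_stage_csv(ps_age, out, "partial_spearman_age.csv"))
    results$characterization <- list(summary = summ, high_frequency = hf,
                                      varpart = vp, pca = pca)
  })

  # --- associations ---------------------------------------------------
  stage("assoc", {
    hf <- results$characterization$high_frequency
    chems <- utils::head(hf, config$n_assoc_chemicals)
    ms <- match_controls(study$cohort, labels, config$outcome)
    rows <- lapply(chems, function(ch) {
      df <- matched_analysis_frame(study$cohort, labels, ms, cmat, ch)
      fit_single_exposure(df, config$outcome, chemical = ch)
    })
    assoc <- do.call(rbind, rows)
    files <- c(files, write_stage_csv(assoc, out, "associations.csv"))
    results$matched <- ms
    results$assoc <- assoc
  })

  # --- mixtures -------------------------------------------------------
  stage("mixture", {
    hf <- results$characterization$high_frequency
    if (length(hf) < 2) stop("need >= 2 high-frequency chemicals")
    ms <- results$matched %||% match_controls(study$cohort, labels, config$outcome)
    df <- merge(as.data.frame(study$cohort), as.data.frame(labels),
                by = "subject_id")
    df <- df[df$subject_id %in% ms$ids, , drop = FALSE]
    qz <- quantize(log10(cmat$conc[df$subject_id, hf, drop = FALSE]))
    covs <- df[, c("region", "age", "sex", "smoking", "drinking")]
    y <- as.integer(df[[config$outcome]])
    wqs <- fit_wqs(qz, y, covariates = covs, direction = "positive",
                   n_boot = config$n_boot, seed = derive_seed(config$seed, 11L))
    qgc <- fit_qgcomp(qz, y, covariates = covs)
    mix <- data.frame(
      model = c("wqs", "qgcomp"),
      direction = c(wqs$direction, qgc$direction),
      beta = c(wqs$beta, qgc$psi), se = c(wqs$se, qgc$se),
      or = c(wqs$or, qgc$or),
      ci_low = c(wqs$ci_or_scale["low"], qgc$ci_or_scale["low"]),
      ci_high = c(wqs$ci_or_scale["high"], qgc$ci_or_scale["high"]),
      p = c(wqs$p, qgc$p), seed = config$seed,
      stringsAsFactors = FALSE)
    wts <- rbind(
      data.frame(model = "wqs", chemical_id = names(wqs$weights),
                 weight = unname(wqs$weights), direction = wqs$direction),
      data.frame(model = "qgcomp",
                 chemical_id = names(c(qgc$weights_positive, qgc$weights_negative)),
                 weight = unname(c(qgc$weights_positive, qgc$weights_negative)),
                 direction = rep(c("positive", "negative"),
                                 c(length(qgc$weights_positive),
                                   length(qgc$weights_negative)))))
    files <- c(files,
      write_stage_csv(mix, out, "mixture_results.csv"),
      write_stage_csv(wts, out, "mixture_weights.csv"))
    results$mixture <- list(wqs = wqs, qgcomp = qgc)
  })

  # --- risk -----------------------------------------------------------
  stage("risk", {
    gv <- panel[!is.na(panel$guidance_value_ng_ml),
                c("chemical_id", "guidance_type", "guidance_value_ng_ml")]
    names(gv) <- c("chemical_id", "type", "value_ng_ml")
    hq <- hazard_quotients(cmat, gv)
    files <- c(files, write_stage_csv(hq$summary, out, "hazard_quotients.csv"))
    ch <- results$assoc$chemical[1]
    ms <- results$matched
    df <- matched_analysis_frame(study$cohort, labels, ms, cmat, ch)
    curve <- tryCatch(
      dose_risk_curve(df, config$outcome, n_knots = config$n_knots),
      error = function(e) NULL)
    if (!is.null(curve)) {
      files <- c(files, write_stage_csv(
        data.frame(chemical_id = ch, grid_ng_ml = curve$grid, or = curve$or,
                   ci_low = curve$ci_low, ci_high = curve$ci_high), out,
        "dose_risk_curve.csv"))
    }
    results$risk <- list(hq = hq, curve = curve)
  })

  manifest <- list(
    package = "serumexposome",
    version = as.character(utils::packageVersion("serumexposome")),
    seed = config$seed,
    stages = config$stages,
    outputs = lapply(stats::setNames(nm = sort(unique(files))), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}
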