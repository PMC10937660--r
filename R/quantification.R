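#' Fit a 1/x-weighted calibration curve for one chemical in one batch
#'
#' Concentration is the independent variable and the analyte/internal-
#' standard area ratio (the relative response) the dependent variable.
#' Weighted least squares with weights 1/x sharpens accuracy at the low end
#' of the ladder; the zero-concentration calibrator is excluded (its weight
#' is undefined). At least 5 positive calibrator levels are required,
#' otherwise the fit is flagged unquantifiable. r-squared is computed on the
#' weighted scale (1 - SSE_w/SST_w), consistent with the 1/x objective.
#'
#' @param conc calibrator concentrations, ng/mL.
#' @param response relative responses (area / is_area), same length.
#' @param weighting only "1/x" is supported.
#' @return list of class `calibration_fit`: slope, intercept, r2, n_levels,
#'   ok, weighting.
#' @export
fit_calibration <- function(conc, response, weighting = "1/x") {
  stopifnot(length(conc) == length(response))
  if (weighting != "1/x") stop_input("unsupported weighting '%s'", weighting)
  keep <- is.finite(conc) & is.finite(response) & conc > 0
  x <- conc[keep]; y <- response[keep]
  n_levels <- length(unique(x))
  if (length(x) >= 2 && stats::var(x) == 0)
    stop_input("singular design: all calibrator concentrations identical")
  if (n_levels < 5) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r2 = NA_real_, n_levels = n_levels, ok = FALSE,
                          weighting = weighting),
                     class = "calibration_fit"))
  }
  if (stats::var(x) == 0) stop_input("singular design: all calibrator concentrations identical")
  w <- 1 / x
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  b <- unname(fit$coefficients)
  ybar_w <- sum(w * y) / sum(w)
  sse <- sum(w * fit$residuals^2)
  sst <- sum(w * (y - ybar_w)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  structure(list(slope = b[2], intercept = b[1], r2 = r2,
                 n_levels = n_levels, ok = is.finite(b[2]) && b[2] > 0,
                 weighting = weighting),
            class = "calibration_fit")
}

#' Estimate the limit of quantification from a calibration ladder
#'
#' The LOQ is the lowest ladder concentration whose mean analyte area
#' exceeds 10 times the chromatogram noise (signal-to-noise strictly > 10).
#' If no rung qualifies the LOQ is +Inf and the chemical is undetectable in
#' that batch.
#'
#' @param conc calibrator concentrations (ascending ladder; zero allowed and
#'   ignored).
#' @param area analyte peak areas at those concentrations.
#' @param noise_sd chromatogram noise level in area units, > 0.
#' @return LOQ in ng/mL (possibly `Inf`).
#' @export
estimate_loq <- function(conc, area, noise_sd) {
  if (length(conc) == 0) stop_input("empty calibration ladder")
  if (!is.finite(noise_sd) || noise_sd <= 0) stop_input("noise_sd must be > 0")
  keep <- conc > 0
  levels <- sort(unique(conc[keep]))
  if (length(levels) == 0) stop_input("empty calibration ladder")
  for (l in levels) {
    sn <- mean(area[conc == l]) / noise_sd
    if (is.finite(sn) && sn > 10) return(l)
  }
  Inf
}

# All calibration fits + LOQs for every (chemical, batch) of one platform's
# peak table. noise_sd: named per-chemical chromatogram noise (area units).
# is_assignment: named chemical -> internal-standard id; chemicals mapped to
# "external" are fit on raw areas (external-standard mode).
calibrate_platform <- function(peaks, noise_sd, is_assignment = NULL) {
  cal <- peaks[peaks$role == "calibrator", , drop = FALSE]
  cal <- cal[cal$chemical_id %in% names(noise_sd), , drop = FALSE]
  out <- list(); i <- 0L
  for (ch in unique(cal$chemical_id)) {
    sub_ch <- cal[cal$chemical_id == ch, , drop = FALSE]
    mode_is <- if (!is.null(is_assignment)) is_assignment[[ch]] %||% sub_ch$is_id[1] else sub_ch$is_id[1]
    for (b in unique(sub_ch$batch)) {
      s <- sub_ch[sub_ch$batch == b, , drop = FALSE]
      rr <- relative_response(s, peaks, mode_is)
      fit <- fit_calibration(s$nominal_conc_ng_ml, rr)
      loq <- estimate_loq(s$nominal_conc_ng_ml, s$area, noise_sd[[ch]])
      i <- i + 1L
      out[[i]] <- data.frame(
        chemical_id = ch, batch = b, platform = s$platform[1],
        slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
        loq = loq, is_id = mode_is %||% "external",
        ok = fit$ok, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Relative response of the rows in `s` under internal standard `is_id`
# (looked up from the IS records in `peaks`); raw area in external mode.
relative_response <- function(s, peaks, is_id) {
  if (is.null(is_id) || is.na(is_id) || identical(is_id, "external"))
    return(s$area)
  is_rows <- peaks[peaks$chemical_id == is_id, , drop = FALSE]
  is_area <- is_rows$area[match(s$sample_id, is_rows$sample_id)]
  s$area / is_area
}

#' Fit all batch-specific calibration curves for a study
#'
#' @param peaks list of peak tables (one per platform) or a single table.
#' @param noise_sd named per-chemical chromatogram noise, area units.
#' @param is_assignment optional named chemical -> internal-standard id
#'   override ("external" selects external-standard mode).
#' @return calibration report data.frame: chemical_id, batch, platform,
#'   slope, intercept, r2, loq, is_id, ok.
#' @export
calibrate_study <- function(peaks, noise_sd, is_assignment = NULL) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  do.call(rbind, lapply(peaks, calibrate_platform, noise_sd = noise_sd,
                        is_assignment = is_assignment))
}

#' Select the internal standard for one chemical
#'
#' Two platform rules. `gc_rt`: the candidate with the smallest absolute
#' retention-time difference (ties go to the earlier-eluting, i.e. first in
#' candidate order after sorting by retention time). `lc_min_rsd`: for each
#' candidate, quantify every QC sample with batch-specific calibration under
#' that candidate and return the candidate minimising the relative standard
#' deviation of the measured/nominal ratio across all QCs; ties break by
#' candidate list order. With no candidates the chemical falls back to the
#' external-standard mode with a warning.
#'
#' @param chemical chemical id.
#' @param candidates candidate internal-standard ids (character).
#' @param mode "gc_rt" or "lc_min_rsd".
#' @param peaks platform peak table (needed for lc_min_rsd).
#' @param rt analyte retention time (gc_rt).
#' @param candidate_rt named candidate retention times (gc_rt).
#' @param noise_sd named chromatogram noise (lc_min_rsd, for LOQ bookkeeping).
#' @return internal-standard id, or "external".
#' @export
select_internal_standard <- function(chemical, candidates,
                                     mode = c("gc_rt", "lc_min_rsd"),
                                     peaks = NULL, rt = NULL,
                                     candidate_rt = NULL, noise_sd = NULL) {
  mode <- match.arg(mode)
  if (length(candidates) == 0) {
    warning(sprintf("no internal-standard candidate for %s: achieved by external standard method",
                    chemical))
    return("external")
  }
  if (mode == "gc_rt") {
    stopifnot(!is.null(rt), !is.null(candidate_rt))
    d <- abs(candidate_rt[candidates] - rt)
    best <- candidates[d == min(d)]
    if (length(best) > 1) {
      # earlier-eluting standard wins ties
      best <- best[order(candidate_rt[best])][1]
    }
    return(unname(best))
  }
  # lc_min_rsd
  stopifnot(!is.null(peaks))
  qc <- peaks[peaks$role == "qc" & peaks$chemical_id == chemical, , drop = FALSE]
  if (length(unique(qc$batch)) < 2)
    stop_input("lc_min_rsd needs QC records spanning >= 2 batches")
  rsds <- vapply(candidates, function(cand) {
    meas <- quantify_qcs_one(chemical, cand, peaks,
                             noise_sd = noise_sd, pooled = TRUE)
    ratio <- meas$measured / meas$nominal
    ratio <- ratio[is.finite(ratio)]
    if (length(ratio) < 2) return(Inf)
    r <- rsd_pct(ratio)
    if (is.na(r)) Inf else r
  }, numeric(1))
  candidates[which.min(rsds)]  # which.min takes the first minimum: list order
}

# Calibrated QC concentrations for one chemical under one candidate
# internal standard. `pooled = TRUE` fits a single calibration over all
# batches: that is the internal-standard *selection* view, where a
# drift-sharing candidate yields zero cross-batch RSD and a non-sharing one
# does not (batch-specific refits would cancel constant within-batch drift
# for any stable candidate and leave nothing to select on).
quantify_qcs_one <- function(chemical, is_id, peaks, noise_sd = NULL,
                             pooled = FALSE) {
  cal <- peaks[peaks$role == "calibrator" & peaks$chemical_id == chemical, , drop = FALSE]
  qc <- peaks[peaks$role == "qc" & peaks$chemical_id == chemical, , drop = FALSE]
  if (pooled) {
    fit <- fit_calibration(cal$nominal_conc_ng_ml,
                           relative_response(cal, peaks, is_id))
    if (!fit$ok) return(data.frame(batch = character(), nominal = numeric(),
                                   measured = numeric()))
    rr <- relative_response(qc, peaks, is_id)
    return(data.frame(batch = qc$batch, nominal = qc$nominal_conc_ng_ml,
                      measured = (rr - fit$intercept) / fit$slope,
                      stringsAsFactors = FALSE))
  }
  out <- list(); i <- 0L
  for (b in unique(qc$batch)) {
    s <- cal[cal$batch == b, , drop = FALSE]
    fit <- fit_calibration(s$nominal_conc_ng_ml, relative_response(s, peaks, is_id))
    if (!fit$ok) next
    q <- qc[qc$batch == b, , drop = FALSE]
    rr <- relative_response(q, peaks, is_id)
    i <- i + 1L
    out[[i]] <- data.frame(batch = b, nominal = q$nominal_conc_ng_ml,
                           measured = (rr - fit$intercept) / fit$slope,
                           stringsAsFactors = FALSE)
  }
  if (i == 0) return(data.frame(batch = character(), nominal = numeric(),
                                measured = numeric()))
  do.call(rbind, out)
}

#' Assign internal standards for a whole panel
#'
#' GC chemicals get the nearest-retention-time standard (static); LC
#' chemicals get the minimum-RSD standard evaluated once on all QCs and then
#' frozen.
#'
#' @param panel panel data.frame with `is_table` attribute.
#' @param peaks named list of platform peak tables.
#' @param noise_sd named per-chemical noise.
#' @return named character vector chemical -> internal-standard id.
#' @export
assign_internal_standards <- function(panel, peaks, noise_sd) {
  is_table <- attr(panel, "is_table")
  out <- character(nrow(panel)); names(out) <- panel$chemical_id
  for (i in seq_len(nrow(panel))) {
    ch <- panel$chemical_id[i]
    pf <- panel$platform[i]
    cands <- strsplit(panel$is_candidates[i], ",")[[1]]
    if (pf == "GC") {
      crt <- stats::setNames(is_table$rt, is_table$is_id)[cands]
      out[i] <- select_internal_standard(ch, cands, "gc_rt",
                                         rt = panel$rt[i], candidate_rt = crt)
    } else {
      out[i] <- select_internal_standard(ch, cands, "lc_min_rsd",
                                         peaks = peaks[[pf]],
                                         noise_sd = noise_sd)
    }
  }
  out
}

#' Quantify study samples with batch-specific calibration
#'
#' Each study sample's relative response is inverted through the calibration
#' curve of its own batch: `conc = (relative_response - intercept) / slope`.
#' Values below the batch LOQ, and negative back-calculated values, are
#' flagged below-LOQ. Cells whose (chemical, batch) has no accepted fit are
#' flagged unquantified (NA), never silently zero.
#'
#' @param peaks named list of platform peak tables (or one table).
#' @param fits calibration report from [calibrate_study()].
#' @return a `concentration_matrix`: list with `conc` (subject x chemical),
#'   `below_loq` and `unquantified` logical matrices, `batch` (character
#'   matrix), `loq` (the fits table), `imputed = FALSE`.
#' @export
quantify_samples <- function(peaks, fits) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  st <- do.call(rbind, lapply(peaks, function(p) {
    p[p$role == "study" & p$chemical_id %in% fits$chemical_id, , drop = FALSE]
  }))
  subjects <- unique(st$sample_id)
  chems <- unique(fits$chemical_id)
  conc <- matrix(NA_real_, length(subjects), length(chems),
                 dimnames = list(subjects, chems))
  below <- matrix(NA, length(subjects), length(chems),
                  dimnames = list(subjects, chems))
  unq <- matrix(TRUE, length(subjects), length(chems),
                dimnames = list(subjects, chems))
  batch_m <- matrix(NA_character_, length(subjects), length(chems),
                    dimnames = list(subjects, chems))
  fits_key <- paste(fits$chemical_id, fits$batch)
  for (pf_tab in peaks) {
    for (ch in intersect(unique(pf_tab$chemical_id), chems)) {
      rows <- pf_tab[pf_tab$role == "study" & pf_tab$chemical_id == ch, , drop = FALSE]
      if (nrow(rows) == 0) next
      for (b in unique(rows$batch)) {
        f <- fits[match(paste(ch, b), fits_key), , drop = FALSE]
        rb <- rows[rows$batch == b, , drop = FALSE]
        batch_m[rb$sample_id, ch] <- b
        if (nrow(f) == 0 || is.na(f$ok) || !f$ok) next
        rr <- relative_response(rb, pf_tab, f$is_id)
        v <- (rr - f$intercept) / f$slope
        bl <- v < f$loq | v < 0
        conc[rb$sample_id, ch] <- v
        below[rb$sample_id, ch] <- bl
        unq[rb$sample_id, ch] <- FALSE
      }
    }
  }
  structure(list(conc = conc, below_loq = below, unquantified = unq,
                 batch = batch_m, loq = fits, imputed = FALSE),
            class = "concentration_matrix")
}

#' Replace below-LOQ concentrations by LOQ/sqrt(2)
#'
#' Below-LOQ cells take the value LOQ/sqrt(2) of their own batch's LOQ;
#' other cells are untouched, and the below-LOQ flags are preserved so
#' detection frequencies are unaffected by imputation. For chemicals with an
#' infinite LOQ in a batch (no rung reached signal-to-noise 10), cells are
#' imputed from `ceiling_loq` if supplied, otherwise they stay NA and are
#' simply 0% detected in that batch.
#'
#' @param cmat a `concentration_matrix` from [quantify_samples()].
#' @param ceiling_loq optional fallback LOQ (ng/mL) for infinite-LOQ batches.
#' @return the matrix, with `imputed = TRUE`.
#' @export
impute_below_loq <- function(cmat, ceiling_loq = NULL) {
  stopifnot(inherits(cmat, "concentration_matrix"))
  fits <- cmat$loq
  fits_key <- paste(fits$chemical_id, fits$batch)
  conc <- cmat$conc
  for (ch in colnames(conc)) {
    for (b in unique(stats::na.omit(cmat$batch[, ch]))) {
      loq <- fits$loq[match(paste(ch, b), fits_key)]
      if (!is.finite(loq)) loq <- ceiling_loq %||% NA_real_
      idx <- which(cmat$batch[, ch] == b & cmat$below_loq[, ch])
      if (length(idx) && is.finite(loq)) conc[idx, ch] <- loq / sqrt(2)
    }
  }
  cmat$conc <- conc
  cmat$imputed <- TRUE
  cmat
}

#' Back-calculated accuracy of each calibration curve at spiked levels
#'
#' Accuracy = measured/nominal x 100\% for QC spikes, per (chemical, batch,
#' level); acceptance band 80--120\%. Levels with no spiked sample in a
#' batch are reported as not evaluated (NA), not as failures.
#'
#' @param fits calibration report.
#' @param peaks named list of platform peak tables.
#' @param levels spike levels (ng/mL) to evaluate; defaults to all observed.
#' @return data.frame: chemical_id, batch, level, accuracy_pct, pass.
#' @export
evaluate_curve_accuracy <- function(fits, peaks, levels = NULL) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  fits_key <- paste(fits$chemical_id, fits$batch)
  out <- list(); i <- 0L
  for (pf_tab in peaks) {
    qc <- pf_tab[pf_tab$role == "qc", , drop = FALSE]
    qc <- qc[qc$chemical_id %in% fits$chemical_id, , drop = FALSE]
    lv <- levels %||% sort(unique(qc$nominal_conc_ng_ml))
    for (ch in unique(qc$chemical_id)) {
      for (b in unique(qc$batch[qc$chemical_id == ch])) {
        f <- fits[match(paste(ch, b), fits_key), , drop = FALSE]
        for (l in lv) {
          rows <- qc[qc$chemical_id == ch & qc$batch == b &
                     qc$nominal_conc_ng_ml == l, , drop = FALSE]
          acc <- NA_real_
          if (nrow(rows) > 0 && nrow(f) == 1 && isTRUE(f$ok)) {
            rr <- relative_response(rows, pf_tab, f$is_id)
            meas <- (rr - f$intercept) / f$slope
            acc <- mean(meas) / l * 100
          }
          i <- i + 1L
          out[[i]] <- data.frame(chemical_id = ch, batch = b, level = l,
                                 accuracy_pct = acc,
                                 pass = if (is.na(acc)) NA else acc >= 80 & acc <= 120,
                                 stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
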