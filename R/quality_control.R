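#' Precision and recovery metrics for QC samples
#'
#' Precision: RSD over all QC measurements of a chemical, computed on the
#' measured/nominal ratio so that QCs spiked at different levels pool on a
#' common scale (with a single spike level this is the plain RSD of the
#' measured concentrations). Acceptance: RSD strictly < 30\%. Recovery:
#' mean measured/nominal x 100\% per spike level, accepted within
#' [80, 120]\%.
#'
#' @param qc data.frame with columns chemical_id, platform, nominal,
#'   measured (QC concentrations after batch-specific quantification).
#' @return list of class `qc_report`: `precision` (per chemical: rsd_pct,
#'   pass_rsd, n), `recovery` (per chemical x level: recovery_pct,
#'   pass_recovery), `platform_summary` (fraction of chemicals passing each
#'   criterion per platform).
#' @export
qc_metrics <- function(qc) {
  stopifnot(all(c("chemical_id", "platform", "nominal", "measured") %in% names(qc)))
  prec <- do.call(rbind, lapply(split(qc, qc$chemical_id), function(s) {
    if (nrow(s) < 2) stop_input("need >= 2 QC measurements per chemical (%s)", s$chemical_id[1])
    ratio <- s$measured / s$nominal
    r <- rsd_pct(ratio)
    data.frame(chemical_id = s$chemical_id[1], platform = s$platform[1],
               rsd_pct = r, pass_rsd = if (is.na(r)) NA else r < 30,
               n = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(prec) <- NULL
  rec <- do.call(rbind, lapply(
    split(qc, list(qc$chemical_id, qc$nominal), drop = TRUE), function(s) {
      rp <- mean(s$measured) / s$nominal[1] * 100
      data.frame(chemical_id = s$chemical_id[1], platform = s$platform[1],
                 level = s$nominal[1], recovery_pct = rp,
                 pass_recovery = rp >= 80 & rp <= 120,
                 stringsAsFactors = FALSE)
    }))
  rownames(rec) <- NULL
  plat <- do.call(rbind, lapply(split(prec, prec$platform), function(s) {
    recs <- rec[rec$platform == s$platform[1], ]
    data.frame(platform = s$platform[1],
               frac_pass_rsd = mean(s$pass_rsd, na.rm = TRUE),
               frac_pass_recovery = mean(
                 tapply(recs$pass_recovery, recs$chemical_id, all),
                 na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(plat) <- NULL
  structure(list(precision = prec, recovery = rec, platform_summary = plat),
            class = "qc_report")
}

#' Between-batch variance fraction of QC values
#'
#' One-way ANOVA decomposition per chemical on log10 values: metric =
#' between-batch sum of squares / total sum of squares, averaged over
#' chemicals. 0 means QCs are identical across batches; 1 means all variance
#' is between batches.
#'
#' @param mat QC x chemical matrix of log10 values (concentrations or areas).
#' @param batch batch label per QC row.
#' @return scalar in [0, 1]; NA when only one batch is present.
#' @export
batch_effect_metric <- function(mat, batch) {
  mat <- as.matrix(mat)
  batch <- as.factor(batch)
  if (nlevels(droplevels(batch)) < 2) return(NA_real_)
  fr <- apply(mat, 2, function(y) {
    keep <- is.finite(y)
    if (sum(keep) < 2) return(NA_real_)
    yy <- y[keep]; bb <- droplevels(batch[keep])
    gm <- mean(yy)
    ssb <- sum(tapply(yy, bb, function(v) length(v) * (mean(v) - gm)^2))
    sst <- sum((yy - gm)^2)
    # numerically constant columns carry no batch information
    if (sst <= length(yy) * (1e-10 * max(1, abs(gm)))^2) 0 else ssb / sst
  })
  mean(fr, na.rm = TRUE)
}

#' Batch-effect assessment before and after correction
#'
#' Compares the between-batch variance fraction of QC values before
#' correction (e.g. log10 raw areas or external-standard concentrations)
#' with the fraction after batch-specific quantification plus internal-
#' standard correction, and returns principal-component scores of the
#' corrected QCs for plotting.
#'
#' @param before,after QC x chemical matrices (log10 scale), same rows.
#' @param batch batch label per QC row.
#' @return list: `metric_before`, `metric_after`, `pca_scores` (QC x PC,
#'   with batch column), `explained` (variance fractions).
#' @export
batch_effect_assessment <- function(before, after, batch) {
  mb <- batch_effect_metric(before, batch)
  ma <- batch_effect_metric(after, batch)
  keep <- apply(after, 2, function(y) all(is.finite(y)) && stats::var(y) > 0)
  scores <- NULL; explained <- NULL
  if (sum(keep) >= 2) {
    p <- stats::prcomp(after[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    scores <- data.frame(batch = batch, p$x, stringsAsFactors = FALSE)
    explained <- p$sdev^2 / sum(p$sdev^2)
  }
  list(metric_before = mb, metric_after = ma,
       pca_scores = scores, explained = explained)
}

#' Quantified QC concentrations for QC reporting
#'
#' Runs the batch-specific quantification machinery on the QC records of the
#' peak tables and returns a long table ready for [qc_metrics()] and
#' [batch_effect_assessment()].
#'
#' @param peaks named list of platform peak tables.
#' @param fits calibration report from [calibrate_study()].
#' @return data.frame: sample_id, chemical_id, platform, batch, nominal,
#'   measured.
#' @export
quantify_qcs <- function(peaks, fits) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  fits_key <- paste(fits$chemical_id, fits$batch)
  out <- list(); i <- 0L
  for (pf_tab in peaks) {
    qc <- pf_tab[pf_tab$role == "qc" & pf_tab$chemical_id %in% fits$chemical_id, , drop = FALSE]
    for (ch in unique(qc$chemical_id)) {
      rows <- qc[qc$chemical_id == ch, , drop = FALSE]
      for (b in unique(rows$batch)) {
        f <- fits[match(paste(ch, b), fits_key), , drop = FALSE]
        if (nrow(f) == 0 || !isTRUE(f$ok)) next
        rb <- rows[rows$batch == b, , drop = FALSE]
        rr <- relative_response(rb, pf_tab, f$is_id)
        i <- i + 1L
        out[[i]] <- data.frame(sample_id = rb$sample_id, chemical_id = ch,
                               platform = rb$platform, batch = b,
                               nominal = rb$nominal_conc_ng_ml,
                               measured = (rr - f$intercept) / f$slope,
                               stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
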