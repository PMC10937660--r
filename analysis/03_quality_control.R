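#!/usr/bin/env Rscript
# QC evaluation: precision (RSD < 30%) and recovery (80-120%) of the spiked
# QC samples after batch-specific quantification, and the batch-effect
# fraction (between-batch ANOVA R2 of QC values) before vs after
# internal-standard correction.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

q <- load_quantified()
qcs <- quantify_qcs(q$study$peaks, q$fits)
rep <- qc_metrics(qcs)
write_result(rep$precision, "qc_precision.csv")
write_result(rep$recovery, "qc_recovery.csv")
print(rep$platform_summary)

for (pf in c("GC", "LC")) {
  rows <- qcs[qcs$platform == pf, ]
  after <- xtabs(log10(pmax(measured, 1e-12) / nominal) ~ sample_id + chemical_id,
                 data = rows)
  raw <- q$study$peaks[[pf]]
  raw <- raw[raw$role == "qc" & raw$chemical_id %in% colnames(after), ]
  before <- xtabs(log10(area / nominal_conc_ng_ml) ~ sample_id + chemical_id,
                  data = raw)
  common <- intersect(rownames(before), rownames(after))
  batch <- raw$batch[match(common, raw$sample_id)]
  be <- batch_effect_assessment(before[common, colnames(after), drop = FALSE],
                                after[common, , drop = FALSE], batch)
  cat(sprintf("%s batch-effect fraction: %.3f before, %.3f after IS correction\n",
              pf, be$metric_before, be$metric_after))
  if (pf == "GC")
    write_result(be$pca_scores[, 1:min(4, ncol(be$pca_scores))],
                 "qc_pca_scores_gc.csv")
}
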