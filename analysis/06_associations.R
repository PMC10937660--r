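#!/usr/bin/env Rscript
# Single-exposure risk models on matched case-control sets: covariate-
# adjusted logistic regression of each high-frequency chemical (odds ratio
# per log10 ng/mL), plus sex-stratified estimates for the primary outcome.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

q <- load_quantified()
cohort <- q$study$cohort
labels <- classify_outcomes(cohort)
outcome <- "hyperlipidemia"

hf <- select_high_frequency(exposure_summary(q$cmat, cohort$region))
ms <- match_controls(cohort, labels, outcome)
rows <- lapply(head(hf, 6), function(ch) {
  df <- matched_analysis_frame(cohort, labels, ms, q$cmat, ch)
  fit_single_exposure(df, outcome, chemical = ch)
})
assoc <- do.call(rbind, rows)
write_result(assoc, "associations.csv")
cat(sprintf("fit %d single-exposure models for %s (n = %d matched pairs)\n",
            nrow(assoc), outcome, length(ms$case_id)))
print(assoc[, c("chemical", "or", "ci_low", "ci_high", "p")], digits = 3)

strat <- suppressWarnings(
  stratified_risk(cohort, labels, q$cmat, hf[1], outcome, strata = "sex"))
write_result(strat, "associations_by_sex.csv")
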