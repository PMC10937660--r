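#!/usr/bin/env Rscript
# Exposure characterization: detection frequencies and the high-frequency
# rule (> 50% in any region), geometric means with 95% CIs, sex differences
# with fold changes and FDR, age correlations adjusted for the other
# factors, variance partitioning across epidemiological factors, and PCA.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

q <- load_quantified()
cohort <- q$study$cohort

summ <- exposure_summary(q$cmat, cohort$region)
write_result(summ, "exposure_summary.csv")
hf <- select_high_frequency(summ)
cat(sprintf("%d of %d chemicals are high-frequency exposures\n",
            length(hf), nrow(summ)))

sd_sex <- stratified_differences(q$cmat, cohort$sex)
write_result(sd_sex, "differences_by_sex.csv")
cat(sprintf("%d chemicals differ notably by sex (q < 0.05 and FC outside [0.8, 1.3])\n",
            sum(sd_sex$notable)))

ps <- partial_spearman(q$cmat, cohort$age,
                       confounders = cohort[, c("sex", "region", "smoking",
                                                "drinking", "income")])
write_result(ps, "partial_spearman_age.csv")

lg <- log10(q$cmat$conc)
ok <- colnames(lg)[apply(lg, 2, function(v) all(is.finite(v)))]
vp <- variance_partition(lg[, ok, drop = FALSE],
                         data.frame(region = factor(cohort$region),
                                    age = cohort$age,
                                    sex = factor(cohort$sex)))
write_result(vp$per_factor, "variance_partition.csv")
cat("variance explained (marginal adjusted R2):\n")
print(transform(vp$per_factor, marginal = round(marginal, 4),
                unique = round(unique, 4)))

pca <- pca_scores(lg[, ok, drop = FALSE])
write_result(data.frame(subject_id = rownames(pca$scores),
                        pca$scores[, 1:min(4, ncol(pca$scores))]),
             "pca_scores.csv")
cat(sprintf("PC1 and PC2 explain %.1f%% and %.1f%% of exposure variance\n",
            100 * pca$explained[1], 100 * pca$explained[2]))
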