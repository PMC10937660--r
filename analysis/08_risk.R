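#!/usr/bin/env Rscript
# Guidance-value health risk: hazard quotients (HQ = C_serum / C_guidance,
# exceedance when HQ > 1) and a restricted-cubic-spline dose-risk curve with
# the minimum concentration at which the estimated odds ratio exceeds 1.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

q <- load_quantified()
cohort <- q$study$cohort
labels <- classify_outcomes(cohort)
panel <- q$study$panel

gv <- panel[!is.na(panel$guidance_value_ng_ml),
            c("chemical_id", "guidance_type", "guidance_value_ng_ml")]
names(gv) <- c("chemical_id", "type", "value_ng_ml")
hq <- hazard_quotients(q$cmat, gv)
write_result(hq$summary, "hazard_quotients.csv")
cat("guidance exceedance percentages:\n")
print(hq$summary, digits = 3)

outcome <- "hyperlipidemia"
hf <- select_high_frequency(exposure_summary(q$cmat, cohort$region))
ms <- match_controls(cohort, labels, outcome)
df <- matched_analysis_frame(cohort, labels, ms, q$cmat, hf[1])
cur <- dose_risk_curve(df, outcome)
write_result(data.frame(chemical_id = hf[1], grid_ng_ml = cur$grid,
                        or = cur$or, ci_low = cur$ci_low,
                        ci_high = cur$ci_high), "dose_risk_curve.csv")
cat(sprintf("dose-risk curve for %s vs %s: anchor %.3g ng/mL, reference risk concentration %s\n",
            hf[1], outcome, cur$anchor,
            ifelse(is.na(cur$reference_concentration), "not reached",
                   sprintf("%.3g ng/mL", cur$reference_concentration))))
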