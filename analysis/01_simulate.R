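#!/usr/bin/env Rscript
# Simulate the demonstration biomonitoring study: an 800-subject cohort from
# 4 regions with 9 epidemiological factors and 9 clinical parameters, and
# long-format peak tables for the two virtual platforms (full calibration
# ladder and interleaved QC spikes in every batch, multiplicative per-batch
# drift shared between each analyte and its matched internal standard).
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_common.R"))

s <- demo_study()

cat(sprintf("cohort: %d subjects, %d regions, %d chemicals (%d GC + %d LC)\n",
            nrow(s$cohort), length(unique(s$cohort$region)),
            nrow(s$panel), sum(s$panel$platform == "GC"),
            sum(s$panel$platform == "LC")))
cat(sprintf("GC peak table: %d rows over %d batches; LC: %d rows over %d batches\n",
            nrow(s$peaks$GC), length(unique(s$peaks$GC$batch)),
            nrow(s$peaks$LC), length(unique(s$peaks$LC$batch))))
cat("bundle written under", BUNDLE, "\n")
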