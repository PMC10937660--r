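# Shared setup for the analysis scripts: the demonstration study (800
# subjects, 10 + 10 chemicals, 4 regions, full-size batch layouts) and a
# helper that rebuilds the quantified atlas from the simulated bundle.
library(serumexposome)

RESULTS <- "results"
BUNDLE <- file.path(RESULTS, "bundle")
SEED <- 20260919L

demo_study <- function() {
  dir.create(BUNDLE, recursive = TRUE, showWarnings = FALSE)
  s <- make_study(demo_config(seed = SEED))
  write_study_bundle(BUNDLE, s)
  s
}

load_quantified <- function(study = demo_study()) {
  noise <- setNames(study$panel$noise_sd_area, study$panel$chemical_id)
  isa <- assign_internal_standards(study$panel, study$peaks, noise)
  fits <- calibrate_study(study$peaks, noise, is_assignment = isa)
  cmat <- impute_below_loq(quantify_samples(study$peaks, fits))
  list(study = study, fits = fits, cmat = cmat, is_assignment = isa)
}

write_result <- function(df, name) {
  dir.create(RESULTS, showWarnings = FALSE)
  path <- file.path(RESULTS, name)
  write.csv(df, path, row.names = FALSE)
  message("wrote ", path)
}
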