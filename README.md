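# serumexposome

Targeted serum biomonitoring campaigns quantify hundreds of environmental
chemicals (organochlorine pesticides, PFAS, PCBs, PAHs, phthalates, phenols,
sweeteners, hormones) in thousands of subjects by GC–MS/MS and LC–MS/MS and
relate them to chronic-disease outcomes. `serumexposome` implements the
statistical chain of such a campaign as a tested R package, for analytical
chemists and environmental epidemiologists who need each step reproducible:

* **Quantification** — per-batch calibration curves of the internal-standard
  relative response on concentration with 1/x weighting
  (`AREA_Cc / AREA_IS = a + b·Cc`, weights `1/Cc`), batch-specific
  back-calculation, signal-to-noise (> 10) limits of quantification, and
  `LOQ/√2` imputation of censored cells with preserved detection flags.
* **Internal-standard assignment** — nearest retention time on the GC
  platform; minimum QC-RSD under pooled calibration on the LC platform, with
  an external-standard fallback.
* **QC** — RSD < 30 % precision, 80–120 % recovery, per-curve accuracy at
  spiked levels, and a batch-effect fraction (between-batch ANOVA R² of QC
  values) before vs after correction, plus QC PCA scores.
* **Outcomes** — the 12 chronic-disease labels from 9 clinical parameters
  (e.g. hyperuricemia at uric acid ≥ 420/360 µmol/L by sex, diabetes at
  HbA1c ≥ 6.5 %, obesity at BMI > 28 kg/m², metabolic syndrome at ≥ 3 of 4
  components), and greedy 1:1 propensity matching on the 9 epidemiological
  factors plus the 5 major diseases.
* **Characterization** — detection frequencies with the strict
  "> 50 % in any region" high-frequency rule, geometric means with log-scale
  t intervals, fold-change/FDR group contrasts, partial Spearman
  correlations, variance partitioning, PCA.
* **Risk models** — covariate-adjusted logistic/linear single-exposure models
  (OR per log10 ng/mL) with age- and sex-stratified refits; from-scratch
  weighted quantile sum regression (bootstrap simplex weights) and quantile
  g-computation (joint effect ψ = Σ coefficients); hazard quotients
  HQ = C_serum/C_guidance with strict HQ > 1 exceedance; restricted-cubic-
  spline dose–risk curves with a minimum-risk-dose extraction.
* **Synthetic study generator** — a first-class module that emulates the
  campaign (calibration ladders, interleaved QC spikes, per-batch drift
  shared between analytes and their internal standards, region/age exposure
  structure, target detection frequencies) with a truth record, so the whole
  chain is testable against known answers.

## Worked example

The numbered scripts under `analysis/` walk a complete study: simulate →
quantify → QC → outcomes → characterize → single-exposure models → mixtures
→ risk. They operate on the demonstration bundle (800 subjects, 10 GC + 10 LC
chemicals, 4 regions, full-size batch layouts):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify.R
Rscript analysis/03_quality_control.R
```

prints, among other things:

```
cohort: 800 subjects, 4 regions, 20 chemicals (10 GC + 10 LC)
GC peak table: 12048 rows over 6 batches; LC: 11616 rows over 4 batches
100 calibration curves fit (100 accepted), median r2 = 0.9973
median relative quantification error above LOQ: 5.41%
GC batch-effect fraction: 0.837 before, 0.262 after IS correction
LC batch-effect fraction: 0.920 before, 0.218 after IS correction
```

The quantification error sits at the injected 5 % area CV — the calibration
chain adds essentially nothing — and internal-standard correction removes
most of the between-batch variance that dominates the raw signals.
`analysis/05_characterize.R` then attributes exposure variance to the
generating factors (region marginal adjusted R² 0.28 versus 0.016 for age in
this bundle), and the later scripts fit the single-exposure, WQS, quantile
g-computation and dose–risk models on matched case–control sets, writing
every table under `results/`.

Programmatic use mirrors the scripts:

```r
library(serumexposome)
s <- make_study(demo_config(seed = 1))
noise <- setNames(s$panel$noise_sd_area, s$panel$chemical_id)
isa <- assign_internal_standards(s$panel, s$peaks, noise)
fits <- calibrate_study(s$peaks, noise, is_assignment = isa)
atlas <- impute_below_loq(quantify_samples(s$peaks, fits))
exposure_summary(atlas, s$cohort$region)
```

or in one call: `run_pipeline(pipeline_config("out/", seed = 1))`, which
writes every stage's CSVs plus a manifest with md5 hashes; reruns with the
same seed are byte-identical.

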