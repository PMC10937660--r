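---
title: "Quantifying and risk-modelling a serum exposome panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and risk-modelling a serum exposome panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumexposome)
```

## The problem

Targeted serum biomonitoring measures hundreds of environmental chemicals
(organochlorine pesticides, PFAS, PCBs, PAHs, phthalates, phenols, ...) in
thousands of subjects by GC- and LC-tandem mass spectrometry, then asks which
exposures track epidemiological factors and which raise chronic-disease risk.
Between the raw peak areas and those epidemiological answers sit several
statistical steps that are easy to get subtly wrong: instrument response
drifts between maintenance cycles (batches), low concentrations are censored
at a limit of quantification, and mixture effects are not identified by
single-chemical models. This package implements that full chain as tested
code, with a synthetic-study generator that reproduces the statistical
structure the chain assumes, so every step can be validated against a known
truth.

## Quantification model

For each chemical and each batch, the calibration curve regresses the
relative response (analyte peak area divided by its internal standard's peak
area) on the calibrator concentration $C_c$ with weights $1/x$:

$$\frac{A_{C_c}}{A_{IS}} = a + b\,C_c, \qquad w_i = 1/C_{c,i}.$$

The $1/x$ weighting equalizes *relative* error across the ladder, which is
what matters when most serum levels sit near the low end. The
zero-concentration calibrator is excluded (its weight is undefined); it is
retained in the peak tables only as a blank. $r^2$ is computed on the
weighted scale, $1 - SSE_w/SST_w$, consistent with the objective actually
minimized. Fits with fewer than 5 positive calibrator levels are flagged
unquantifiable, and accepted fits require a positive slope.

A study sample's concentration is the inverse of its **own batch's** curve,
$\hat C = (A_s/A_{IS} - a)/b$. Because the internal standard is co-spiked
into every injection and shares the analyte's batch drift, the area ratio
cancels the drift exactly; the per-batch refit absorbs whatever the ratio
does not. The limit of quantification is the lowest ladder rung whose mean
area exceeds 10 times the chromatogram noise (strictly), per batch;
concentrations below it (or negative back-calculations, which are physically
impossible values) are set to $LOQ/\sqrt{2}$, with the censoring flags kept
so detection frequencies never depend on the imputation.

### Internal-standard selection

GC chemicals take the candidate standard nearest in retention time (ties go
to the earlier-eluting one) — a static chemistry-driven rule. LC chemicals
take the candidate minimizing the RSD of calibrated QC concentrations. One
subtlety discovered while testing: if the selection step quantifies QCs with
batch-specific refits, *any* stable candidate cancels a constant
within-batch drift and the RSDs no longer discriminate. The selection
therefore evaluates candidates under a single pooled calibration across
batches, where only a genuinely drift-sharing standard yields zero
cross-batch RSD; batch-specific curves are still used for all downstream
quantification. Chemicals with no candidate fall back to the external-
standard mode (raw areas), with a warning.

## QC evaluation

Precision is the RSD of measured/nominal over all QC injections of a
chemical (equivalent to the plain concentration RSD at a single spike
level), accepted strictly below 30%; recovery is mean measured/nominal per
spike level, accepted within 80–120%. The batch-effect diagnostic is a
one-way ANOVA decomposition on log10 QC values: between-batch sum of squares
over total, averaged over chemicals. It is 0 when QCs are identical across
batches and 1 when all variance is between batches, and on noiseless
drift-sharing data it is exactly 0 after IS correction. PCA score tables of
the corrected QCs are exported for the usual visual check.

## Outcomes and matching

The 12 outcome labels apply the clinical thresholds exactly as printed
(all $\ge$ comparisons except obesity, which is strictly $>$ 28 kg/m²);
hypertension and hyperlipidemia are disjunctions of their components, and
metabolic syndrome requires at least 3 of {abdominal obesity,
hypertriglyceridemia, hypertension, diabetes}. Missing parameters propagate
to missing labels rather than silently healthy ones. For each outcome,
subjects with more than two diseases are excluded (waived for metabolic
syndrome, itself a multi-disease state); the count is taken over all 12
labels, since no narrower set is canonical. Controls are matched 1:1 without
replacement by greedy nearest neighbour on the logit of a propensity score
(logistic model of case status on the 9 epidemiological factors plus the
five major-disease indicators), processing cases in descending score order.
No caliper is applied by default (none is stated in the field protocols this
mirrors); a caliper argument exists. Distances on the logit scale are the
default because they spread the tails of the score distribution; the raw
scale is available as an option.

## Characterization choices

* Detection means *not below LOQ*; a chemical is a high-frequency exposure
  when any region's detection frequency strictly exceeds 50%.
* Geometric means are reported with a log-scale t interval: the CI method is
  not standardized in biomonitoring reports, and the t interval is exact
  under log-normality, which is also the generator's model.
* Group contrasts use geometric-mean fold changes with two-sided rank-sum
  tests and Benjamini–Hochberg adjustment; a contrast is flagged notable when
  q < 0.05 *and* the fold change leaves [0.8, 1.3].
* Partial rank correlations residualize the ranks of both the factor and the
  chemical on the ranks of the other factors and correlate the residuals,
  with a t-approximation p value on n − 2 − k degrees of freedom.
* Variance partitioning uses redundancy analysis on the scaled log10 matrix;
  both the marginal adjusted R² of each factor alone and its unique
  contribution (joint minus joint-without-it) are reported, since published
  single-number fractions are usually ambiguous between the two.

## Mixture models

Both mixture models quantize each chemical to quartile scores 0–3 (type-7
empirical quantiles; ties go to the lower class, so an all-tied chemical is
constant 0, and scores are invariant to monotone transforms).

**Weighted quantile sum.** For a fixed direction, the index
$z_i = \sum_j w_j q_{ij}$ with $w \ge 0$, $\sum w = 1$ is estimated by
maximizing the logistic likelihood of the outcome on $z$ plus covariates;
the simplex is parameterized by a softmax, and a quadratic penalty keeps the
index coefficient on the requested side. Weights are estimated on bootstrap
resamples of a 40% training split and aggregated with weights proportional
to each bootstrap's squared index z-statistic (a common convention; a plain
mean is a switch), then the final index is refit on the 60% validation
split. The outcome model is the logistic likelihood even though some WQS
descriptions say "linear": odds ratios $e^\beta$ only make sense under the
logit link. Confidence intervals are reported two ways: the OR-scale form
$OR \pm 1.96\,SE(OR)$ (the literal convention of the biomonitoring reports
this mirrors, kept as the default for fidelity despite being statistically
unconventional — it can produce negative lower bounds) and the conventional
$\exp(\beta \pm 1.96\,se)$.

**Quantile g-computation** fits one generalized linear model on all
quantized chemicals plus covariates; the joint effect $\psi$ is the sum of
the per-chemical coefficients — the effect of raising every chemical one
quartile simultaneously — with a delta-method standard error, and weights
are the coefficients normalized within their sign groups, so opposing
directions coexist in one run. Rank-deficient (collinear) quantized designs
are ridge-stabilized with a warning. Bayesian kernel machine regression is
deliberately not implemented; `fit_bkmr()` says so.

## Risk assessment

Hazard quotients are $HQ = C_{serum}/C_{guidance}$ per subject and chemical
with exceedance strictly above 1; only serum-equivalent guidance values
(BE, HBM-II, BGV, or RfD with a supplied conversion) are accepted — no
internal pharmacokinetics. Dose–risk curves fit a logistic model on a
natural (restricted) cubic spline of log10 concentration with knots at the
5/35/65/95% exposure quantiles — a standard placement when the source
protocol names only software. The curve reports OR(c) against a reference
anchor (the sample median; OR(anchor) = 1 by construction) with a
delta-method band, and the *reference risk concentration* is the smallest
grid concentration above the anchor whose estimated OR exceeds 1 and stays
above 1 for the rest of the observed range — the point-estimate criterion,
with a stricter CI-lower-bound option. With no interior knots the curve
degenerates exactly to the single-exposure logistic model.

## The synthetic study

The generator emulates the study conditions end to end: a 5696-subject
default cohort from 15 regions with the marginals of a large Chinese
chronic-disease cohort (sex ratio 2607/3089, age 51 ± 17, clinical
parameters at their published means), GC batches of 158 real + 21 QC
samples against a 13-level 0–100 ng/mL ladder, LC batches of 264 + 24
against an 18-level 0–200 ng/mL ladder, QC spikes cycling the accuracy
levels (2/5/20 GC, 1/10/100 LC). Exposures are log-normal:

$$\log_{10} C_{ij} = \mu_j + r_j(\text{region}_i) + s_j\,(\text{age}_i-50)
  + \varepsilon_{ij},$$

with region offsets (SD 0.3 log10) dominating the age trend (≈0.004
log10/year) so that variance partitioning attributes most explained
variance to region, as real campaigns find. Sampling month is assigned per
region block, reproducing the region/month confounding of region-by-region
fieldwork. Each chemical's baseline $\mu_j$ is solved by root finding so its
expected detection frequency — against the *realized* per-batch LOQs implied
by drift, response factor and noise floor — hits a target drawn from
U(0.15, 1). Areas are `response_factor × concentration × batch_drift ×
(1 + ε)` with multiplicative Gaussian noise (CV 5% by default, truncated at
−0.99 so areas stay positive, matching RSD-style QC metrics); internal
standards carry the same batch drift, which is the property IS correction
exploits. Batch counts are `ceiling(n_study / real_per_batch)` — published
batch totals are not force-matched, since the printed totals are not
mutually consistent. Binary outcomes for effect-recovery experiments come
from a logistic link on log10 true concentrations with configurable
log odds ratios (defaults drawn from U(0.3, 0.7) for a handful of
chemicals) and an intercept solved for a target prevalence.

What the generator does *not* emulate: chromatogram-level structure
(peak shapes, retention drift, co-elution), matrix effects that differ
between calibrators and serum, correlated exposures within chemical classes,
and exposure-dependent clinical parameters (outcome labels derived from the
clinical table are independent of exposure unless effects are injected
explicitly). Passing tests therefore certify the statistical machinery, not
instrument physics or real-world confounding structure.

## Problem sizes and numerics

The test suite and the acceptance script run deliberately scaled-down
studies: recovery checks use 500 subjects × 20 chemicals × 3 batches
(drift SD 0.4, so up to roughly threefold batch drift), effect-recovery
simulations use n = 2000–5000, WQS uses 200 bootstraps at 4 chemicals, and
the end-to-end demonstration bundle is 800 subjects × 20 chemicals — sizes
chosen so the whole chain, including the paper-scale batch layouts, is
exercised in minutes on one core while leaving the estimators enough data to
recover their targets. Numerical guards worth knowing: the batch-effect
metric treats numerically constant columns (total SS below a relative
epsilon) as contributing 0; WQS aggregates only converged bootstraps and
flags the fit unstable when more than half fail; near-separation logistic
fits are flagged non-converged rather than reported; and the bundle writer
serializes numerics at 17 significant digits so a bundle round-trips
losslessly.
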