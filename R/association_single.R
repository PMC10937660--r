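#' Single-exposure disease-risk model on a matched case--control set
#'
#' Binary outcomes: maximum-likelihood logistic regression of case status on
#' log10 exposure plus the nine epidemiological covariates; odds ratios are
#' per one-unit increase in log10 concentration, with Wald confidence
#' intervals. Continuous clinical parameters: least-squares linear
#' regression with the same covariates. Perfect separation or
#' non-convergence is flagged, not reported as a number.
#'
#' @param data data.frame holding the outcome/parameter, the covariates and
#'   a column `log10_exposure` (already log10-transformed, imputed).
#' @param response name of the outcome (binary 0/1/logical) or clinical
#'   parameter (numeric) column.
#' @param covariates covariate names; default the 9 epidemiological factors.
#' @param chemical label carried into the result.
#' @param stratum label carried into the result.
#' @return one-row data.frame of class `association_result`: chemical,
#'   outcome, model, beta, se, or, ci_low, ci_high, p, n_cases, n_controls,
#'   converged, hl_p (Hosmer-Lemeshow goodness-of-fit p, logistic only),
#'   stratum.
#' @export
fit_single_exposure <- function(data, response, covariates = epi_factors(),
                                chemical = NA_character_,
                                stratum = "all") {
  stopifnot("log10_exposure" %in% names(data))
  if (stats::var(data$log10_exposure, na.rm = TRUE) == 0)
    stop_input("zero exposure variance")
  data <- encode_covariates(data)
  covariates <- intersect(covariates, names(data))
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]][!is.na(data[[v]])])) > 1, logical(1))]
  form <- stats::as.formula(paste(
    response, "~ log10_exposure",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  y <- data[[response]]
  binary <- is.logical(y) || all(y[!is.na(y)] %in% c(0, 1))
  if (binary) {
    data[[response]] <- as.integer(y)
    w <- withCallingHandlers(
      fit <- stats::glm(form, family = stats::binomial(), data = data),
      warning = function(w) invokeRestart("muffleWarning"))
    converged <- fit$converged &&
      !any(abs(stats::coef(fit)) > 20, na.rm = TRUE)
    model <- "logistic"
  } else {
    fit <- stats::lm(form, data = data)
    converged <- TRUE
    model <- "linear"
  }
  sm <- summary(fit)$coefficients
  beta <- sm["log10_exposure", 1]
  se <- sm["log10_exposure", 2]
  p <- sm["log10_exposure", 4]
  hl <- if (model == "logistic" && converged)
    hosmer_lemeshow(fit$y, stats::fitted(fit)) else NA_real_
  if (!converged) { beta <- se <- p <- NA_real_ }
  res <- data.frame(
    chemical = chemical, outcome = response, model = model,
    beta = beta, se = se,
    or = if (model == "logistic") exp(beta) else NA_real_,
    ci_low = if (model == "logistic") exp(beta - 1.96 * se) else beta - 1.96 * se,
    ci_high = if (model == "logistic") exp(beta + 1.96 * se) else beta + 1.96 * se,
    p = p,
    n_cases = if (binary) sum(data[[response]] == 1, na.rm = TRUE) else NA_integer_,
    n_controls = if (binary) sum(data[[response]] == 0, na.rm = TRUE) else NA_integer_,
    converged = converged, hl_p = hl, stratum = stratum,
    stringsAsFactors = FALSE)
  class(res) <- c("association_result", "data.frame")
  res
}

# Hosmer-Lemeshow goodness-of-fit test by deciles of fitted risk.
hosmer_lemeshow <- function(y, phat, g = 10) {
  y <- as.numeric(y)
  br <- unique(stats::quantile(phat, probs = seq(0, 1, length.out = g + 1)))
  if (length(br) < 3) return(NA_real_)
  grp <- cut(phat, br, include.lowest = TRUE)
  obs <- tapply(y, grp, sum)
  expd <- tapply(phat, grp, sum)
  n <- tapply(y, grp, length)
  chi <- sum((obs - expd)^2 / (expd * (1 - expd / n)), na.rm = TRUE)
  stats::pchisq(chi, df = length(levels(grp)) - 2, lower.tail = FALSE)
}

#' Assemble the analysis frame for one chemical and one matched set
#'
#' @param cohort cohort table.
#' @param labels outcome labels.
#' @param matched a `matched_set`.
#' @param cmat imputed `concentration_matrix`.
#' @param chemical chemical id.
#' @return data.frame restricted to the matched subjects with a
#'   `log10_exposure` column and a 0/1 outcome column.
#' @export
matched_analysis_frame <- function(cohort, labels, matched, cmat, chemical) {
  df <- merge(as.data.frame(cohort), as.data.frame(labels), by = "subject_id")
  df <- df[df$subject_id %in% matched$ids, , drop = FALSE]
  df$log10_exposure <- log10(cmat$conc[df$subject_id, chemical])
  df
}

#' Age bin used for stratified risk analysis
#'
#' Bins [30, 50), [50, 60), [60, 80]; ages outside return NA.
#' @param age numeric years.
#' @return factor with levels "30-50", "50-60", "60-80".
#' @export
age_stratum <- function(age) {
  cut(age, breaks = c(30, 50, 60, 80.0000001), right = FALSE,
      labels = c("30-50", "50-60", "60-80"), include.lowest = FALSE)
}

#' Stratified single-exposure risk
#'
#' Matching and the logistic fit are rerun within each stratum (age bins
#' 30-50 / 50-60 / 60-80, or sex). Empty or case-free strata are skipped
#' with a warning.
#'
#' @param cohort cohort table.
#' @param labels outcome labels.
#' @param cmat imputed `concentration_matrix`.
#' @param chemical chemical id.
#' @param outcome outcome name.
#' @param strata "age" or "sex".
#' @param covariates covariates for the within-stratum fit (the stratifier
#'   is dropped automatically).
#' @return data.frame of `association_result` rows, one per stratum.
#' @export
stratified_risk <- function(cohort, labels, cmat, chemical, outcome,
                            strata = c("age", "sex"),
                            covariates = epi_factors()) {
  strata <- match.arg(strata)
  if (strata == "age") {
    grp <- age_stratum(cohort$age)
    covs <- setdiff(covariates, "age")
  } else {
    grp <- factor(cohort$sex)
    covs <- setdiff(covariates, "sex")
  }
  out <- list()
  for (s in levels(grp)) {
    idx <- which(!is.na(grp) & grp == s)
    if (length(idx) == 0) { warning(sprintf("stratum %s empty, skipped", s)); next }
    sub <- cohort[idx, , drop = FALSE]
    sublab <- labels[labels$subject_id %in% sub$subject_id, , drop = FALSE]
    ms <- tryCatch(match_controls(sub, sublab, outcome, covariates = covs),
                   error = function(e) NULL)
    if (is.null(ms)) { warning(sprintf("stratum %s unmatched, skipped", s)); next }
    df <- matched_analysis_frame(sub, sublab, ms, cmat, chemical)
    out[[s]] <- fit_single_exposure(df, outcome, covariates = covs,
                                    chemical = chemical, stratum = s)
  }
  do.call(rbind, out)
}
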