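#' Classify the 12 chronic-disease outcomes from the 9 clinical parameters
#'
#' Thresholds applied exactly as printed clinical criteria:
#' hyperuricemia (uric acid >= 420 umol/L in males, >= 360 in females),
#' diabetes (HbA1c >= 6.5\%), high LDL-C (>= 3.4 mmol/L),
#' hypertriglyceridemia (>= 2.3 mmol/L), hypercholesterolemia
#' (>= 6.2 mmol/L), high SBP (>= 140 mmHg), high DBP (>= 90 mmHg),
#' abdominal obesity (waistline >= 90 cm in males, >= 85 in females),
#' obesity (BMI strictly > 28 kg/m2). Composites: hypertension = high SBP or
#' high DBP; hyperlipidemia = high LDL-C or hypertriglyceridemia or
#' hypercholesterolemia; metabolic syndrome = at least 3 of abdominal
#' obesity, hypertriglyceridemia, hypertension and diabetes. Missing
#' parameters propagate NA (labels are missing, never silently FALSE).
#'
#' @param cohort a cohort table with sex and the 9 clinical parameters.
#' @return data.frame of class `outcome_labels`: subject_id, the 12 logical
#'   labels, and disease_count (count over all 12, NA if not decidable).
#' @export
classify_outcomes <- function(cohort) {
  if (!all(cohort$sex %in% c("M", "F", NA)))
    stop_input("classification error: unknown sex code")
  male <- cohort$sex == "M"

  hyperuricemia <- ifelse(male, cohort$uric_acid >= 420, cohort$uric_acid >= 360)
  diabetes <- cohort$hba1c >= 6.5
  hyper_ldl_c <- cohort$ldl_c >= 3.4
  hypertriglyceridemia <- cohort$triglycerides >= 2.3
  hypercholesterolemia <- cohort$total_cholesterol >= 6.2
  high_sbp <- cohort$sbp >= 140
  high_dbp <- cohort$dbp >= 90
  abdominal_obesity <- ifelse(male, cohort$waistline >= 90, cohort$waistline >= 85)
  obesity <- cohort$bmi > 28

  hypertension <- high_sbp | high_dbp
  hyperlipidemia <- hyper_ldl_c | hypertriglyceridemia | hypercholesterolemia
  # >= 3 of the 4 component diseases; decidable under partial missingness.
  comp <- cbind(abdominal_obesity, hypertriglyceridemia, hypertension, diabetes)
  n_true <- rowSums(comp, na.rm = TRUE)
  n_possible <- n_true + rowSums(is.na(comp))
  metabolic_syndrome <- ifelse(n_true >= 3, TRUE,
                               ifelse(n_possible < 3, FALSE, NA))

  lab <- data.frame(
    subject_id = cohort$subject_id,
    hyperuricemia, diabetes, hyper_ldl_c, hypertriglyceridemia,
    hypercholesterolemia, high_sbp, high_dbp, abdominal_obesity, obesity,
    hypertension, hyperlipidemia, metabolic_syndrome,
    stringsAsFactors = FALSE)
  m <- as.matrix(lab[outcome_names()])
  cnt <- rowSums(m, na.rm = TRUE)
  cnt[apply(is.na(m), 1, any)] <- NA  # not decidable under missingness
  lab$disease_count <- cnt
  class(lab) <- c("outcome_labels", "data.frame")
  lab
}

#' Names of the 12 chronic-disease outcome labels
#' @export
outcome_names <- function() {
  c("hyperuricemia", "diabetes", "hyper_ldl_c", "hypertriglyceridemia",
    "hypercholesterolemia", "high_sbp", "high_dbp", "abdominal_obesity",
    "obesity", "hypertension", "hyperlipidemia", "metabolic_syndrome")
}

#' The five major chronic diseases used in control matching
#' @export
major_diseases <- function() {
  c("obesity", "hypertension", "diabetes", "hyperuricemia", "hyperlipidemia")
}

#' Propensity-score matched 1:1 case--control set for one outcome
#'
#' Subjects with more than 2 of the 12 diseases are excluded (waived when
#' the outcome is metabolic syndrome). A logistic propensity model of case
#' status on the 9 epidemiological factors plus the five major-disease
#' indicators is fit on the eligible pool, and controls are matched greedily
#' 1:1 without replacement on the logit of the propensity score, processing
#' cases in descending score order. No caliper by default.
#'
#' @param cohort cohort table.
#' @param labels outcome labels from [classify_outcomes()].
#' @param outcome one of [outcome_names()].
#' @param covariates matching covariates; default the 9 epidemiological
#'   factors.
#' @param caliper optional maximum logit-score distance (default Inf).
#' @param distance "logit" (default) or "raw" propensity scale.
#' @return list of class `matched_set`: outcome, case_id, control_id,
#'   covariates, model (the propensity glm), ids (all matched subjects).
#' @export
match_controls <- function(cohort, labels, outcome,
                           covariates = epi_factors(),
                           caliper = Inf, distance = c("logit", "raw")) {
  distance <- match.arg(distance)
  stopifnot(outcome %in% outcome_names())
  df <- merge(as.data.frame(cohort), as.data.frame(labels), by = "subject_id")
  if (outcome != "metabolic_syndrome") {
    df <- df[!is.na(df$disease_count) & df$disease_count <= 2, , drop = FALSE]
  }
  df <- df[!is.na(df[[outcome]]), , drop = FALSE]
  df$case <- as.integer(df[[outcome]])
  if (sum(df$case == 1) < 1 || sum(df$case == 0) < 1)
    stop_input("need >= 1 case and >= 1 eligible control for %s", outcome)
  if (sum(df$case == 0) < sum(df$case == 1))
    stop_input("fewer eligible controls (%d) than cases (%d) for %s",
               sum(df$case == 0), sum(df$case == 1), outcome)

  df <- encode_covariates(df)
  form <- stats::as.formula(paste(
    "case ~", paste(c(model_terms(covariates),
                      setdiff(major_diseases(), outcome)), collapse = " + ")))
  ps_model <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                          data = df))
  ps <- stats::fitted(ps_model)
  score <- if (distance == "logit") stats::qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12)) else ps

  case_idx <- which(df$case == 1)
  ctrl_idx <- which(df$case == 0)
  case_idx <- case_idx[order(score[case_idx], decreasing = TRUE)]
  avail <- rep(TRUE, length(ctrl_idx))
  pairs <- matrix(NA_integer_, length(case_idx), 2)
  for (k in seq_along(case_idx)) {
    d <- abs(score[ctrl_idx] - score[case_idx[k]])
    d[!avail] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > caliper) next
    pairs[k, ] <- c(case_idx[k], ctrl_idx[j])
    avail[j] <- FALSE
  }
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  structure(list(outcome = outcome,
                 case_id = df$subject_id[pairs[, 1]],
                 control_id = df$subject_id[pairs[, 2]],
                 covariates = covariates,
                 model = ps_model,
                 ids = c(df$subject_id[pairs[, 1]], df$subject_id[pairs[, 2]])),
            class = "matched_set")
}

# Ordinal/categorical covariate encoding shared by the propensity and risk
# models: education enters as an integer score, months/regions as factors.
encode_covariates <- function(df) {
  if ("education" %in% names(df) && !is.numeric(df$education)) {
    df$education <- match(df$education,
                          c("primary", "junior_high", "high_school", "university"))
  }
  for (v in c("sex", "region", "sampling_month", "marital_status",
              "smoking", "drinking")) {
    if (v %in% names(df) && !is.factor(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  df
}

model_terms <- function(covariates) covariates

#' Standardized mean differences of matching covariates
#'
#' Balance diagnostic: |mean(case) - mean(control)| / pooled SD, per
#' covariate column of the model matrix, before and after matching.
#'
#' @param cohort cohort table.
#' @param labels outcome labels.
#' @param matched a `matched_set`.
#' @return data.frame: covariate, smd_before, smd_after.
#' @export
matching_balance <- function(cohort, labels, matched) {
  df <- merge(as.data.frame(cohort), as.data.frame(labels), by = "subject_id")
  df <- df[!is.na(df[[matched$outcome]]), ]
  df <- encode_covariates(df)
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(matched$covariates, collapse = "+"))),
    df)[, -1, drop = FALSE]
  case <- df[[matched$outcome]]
  smd <- function(keep) {
    vapply(colnames(mm), function(cl) {
      x <- mm[keep, cl]; g <- case[keep]
      s <- sqrt((stats::var(x[g]) + stats::var(x[!g])) / 2)
      if (!is.finite(s) || s == 0) return(0)
      abs(mean(x[g]) - mean(x[!g])) / s
    }, numeric(1))
  }
  before <- smd(rep(TRUE, nrow(df)))
  in_set <- df$subject_id %in% matched$ids
  after <- smd(in_set)
  data.frame(covariate = colnames(mm), smd_before = unname(before),
             smd_after = unname(after), stringsAsFactors = FALSE)
}
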