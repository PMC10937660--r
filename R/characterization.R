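#' Detection frequencies overall and per region
#'
#' Detection means not-below-LOQ (flag-based), so LOQ/sqrt(2) imputation
#' never changes frequencies. A chemical is a high-frequency exposure when
#' its detection frequency is strictly greater than 50\% in at least one
#' region.
#'
#' @param cmat a `concentration_matrix` (flags are used, values ignored).
#' @param region region label per subject, aligned with the matrix rows.
#' @return data.frame: chemical_id, freq_total_pct, freq_max_region_pct,
#'   max_region, high_frequency, plus one `freq_<region>` column per region.
#' @export
detection_frequency <- function(cmat, region) {
  flags <- cmat$below_loq
  stopifnot(length(region) == nrow(flags))
  regions <- sort(unique(region))
  det <- !flags  # NA where unmeasured
  total <- 100 * colMeans(det, na.rm = TRUE)
  per_region <- sapply(regions, function(r)
    100 * colMeans(det[region == r, , drop = FALSE], na.rm = TRUE))
  if (is.null(dim(per_region))) per_region <- t(per_region)
  maxr <- apply(per_region, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  which_max <- regions[apply(per_region, 1, function(v)
    if (all(is.na(v))) NA_integer_ else which.max(v))]
  out <- data.frame(chemical_id = colnames(flags),
                    freq_total_pct = unname(total),
                    freq_max_region_pct = unname(maxr),
                    max_region = which_max,
                    high_frequency = unname(maxr > 50),
                    stringsAsFactors = FALSE)
  colnames(per_region) <- paste0("freq_", regions)
  cbind(out, as.data.frame(per_region, row.names = NULL))
}

#' High-frequency chemical selection
#'
#' @param summary a [detection_frequency()] table.
#' @return chemical ids with regional detection frequency strictly > 50\%.
#' @export
select_high_frequency <- function(summary) {
  summary$chemical_id[!is.na(summary$high_frequency) & summary$high_frequency]
}

#' Geometric mean, 95\% confidence interval and median
#'
#' GM = exp(mean(ln x)); the CI is a t interval on the log scale,
#' exponentiated. All values must be positive (run imputation first).
#'
#' @param x positive concentrations, ng/mL.
#' @return list: gm, ci_low, ci_high, median, n.
#' @export
geometric_summary <- function(x) {
  x <- x[!is.na(x)]
  if (any(x <= 0)) stop_input("geometric summary needs positive values; impute below-LOQ cells first")
  lx <- log(x)
  n <- length(lx)
  m <- mean(lx)
  se <- stats::sd(lx) / sqrt(n)
  if (n < 2 || !is.finite(se)) se <- 0
  tq <- if (n >= 2) stats::qt(0.975, n - 1) else 0
  list(gm = exp(m), ci_low = exp(m - tq * se), ci_high = exp(m + tq * se),
       median = stats::median(x), n = n)
}

#' Concentration summary table for a panel
#'
#' Detection frequencies plus geometric means with 95\% CIs and medians, the
#' columns of a biomonitoring concentration atlas. Medians of chemicals
#' detected in fewer than half the subjects are reported as NA
#' (below LOQ).
#'
#' @param cmat imputed `concentration_matrix`.
#' @param region region label per subject.
#' @return data.frame, one row per chemical.
#' @export
exposure_summary <- function(cmat, region) {
  det <- detection_frequency(cmat, region)
  gs <- lapply(colnames(cmat$conc), function(ch) {
    v <- cmat$conc[, ch]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(list(gm = NA, ci_low = NA, ci_high = NA,
                                    median = NA, n = 0))
    geometric_summary(v)
  })
  det$gm <- vapply(gs, function(g) g$gm, numeric(1))
  det$ci_low <- vapply(gs, function(g) g$ci_low, numeric(1))
  det$ci_high <- vapply(gs, function(g) g$ci_high, numeric(1))
  det$median <- ifelse(det$freq_total_pct >= 50,
                       vapply(gs, function(g) g$median, numeric(1)), NA)
  det
}

#' Group differences in exposure with fold changes and FDR control
#'
#' For a binary grouping (sex, or smoking/drinking restricted to males),
#' per chemical: fold change of geometric means (group1/group2), a two-sided
#' Wilcoxon rank-sum test, and Benjamini-Hochberg adjusted q values across
#' chemicals. A chemical is "notable" when q < 0.05 and the fold change is
#' outside [0.8, 1.3].
#'
#' @param cmat imputed `concentration_matrix`.
#' @param group binary factor per subject (first level = group1).
#' @return data.frame: chemical_id, fold_change, p, q, notable.
#' @export
stratified_differences <- function(cmat, group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2, length(group) == nrow(cmat$conc))
  if (any(table(group) < 3)) stop_input("each group needs n >= 3")
  lv <- levels(group)
  res <- do.call(rbind, lapply(colnames(cmat$conc), function(ch) {
    v <- cmat$conc[, ch]
    g1 <- v[group == lv[1] & !is.na(v)]
    g2 <- v[group == lv[2] & !is.na(v)]
    if (length(g1) == 0 || length(g2) == 0) stop_input("empty group for %s", ch)
    fc <- gmean(g1) / gmean(g2)
    p <- suppressWarnings(stats::wilcox.test(g1, g2)$p.value)
    data.frame(chemical_id = ch, fold_change = fc, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$notable <- res$q < 0.05 & (res$fold_change < 0.8 | res$fold_change > 1.3)
  res
}

#' Partial Spearman correlation of one factor with each chemical
#'
#' All variables are rank-transformed; the factor and each chemical are
#' residualized on the confounder ranks by least squares and the Pearson
#' correlation of the residuals is reported, with a t-approximation p value
#' (df = n - 2 - number of confounder columns) and Benjamini-Hochberg q
#' across chemicals.
#'
#' @param cmat imputed `concentration_matrix`.
#' @param factor_values numeric or ordinal-coded factor per subject.
#' @param confounders data.frame of confounders (coded numerically or as
#'   factors; factors expand to dummy columns).
#' @return data.frame: chemical_id, rho, p, q.
#' @export
partial_spearman <- function(cmat, factor_values, confounders = NULL) {
  x <- as.numeric(factor_values)
  if (length(unique(x[!is.na(x)])) < 2) stop_input("constant factor: correlation undefined")
  n <- nrow(cmat$conc)
  if (!is.null(confounders)) {
    cf <- as.data.frame(confounders)
    mm <- stats::model.matrix(~ ., data = cf)[, -1, drop = FALSE]
    mm <- apply(mm, 2, rank)
    k <- ncol(mm)
  } else {
    mm <- NULL; k <- 0
  }
  if (n <= k + 2) stop_input("need n > #confounders + 2")
  rx <- rank(x)
  ex <- if (is.null(mm)) rx - mean(rx) else stats::lm.fit(cbind(1, mm), rx)$residuals
  res <- do.call(rbind, lapply(colnames(cmat$conc), function(ch) {
    ry <- rank(cmat$conc[, ch])
    ey <- if (is.null(mm)) ry - mean(ry) else stats::lm.fit(cbind(1, mm), ry)$residuals
    rho <- stats::cor(ex, ey)
    df <- n - 2 - k
    tval <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df)
    data.frame(chemical_id = ch, rho = rho, p = p, stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Variance of the exposure matrix explained by epidemiological factors
#'
#' Redundancy-analysis partitioning of the column-scaled log10 exposure
#' matrix: for each factor, the adjusted R-squared of the multivariate
#' regression on that factor alone (its marginal fraction) and the drop in
#' joint adjusted R-squared when it is removed (its unique fraction), plus
#' the joint fraction of all factors together.
#'
#' @param logmat subjects x chemicals matrix of log10 concentrations.
#' @param factors data.frame of factors (one column each; factors or
#'   numerics).
#' @return list: `per_factor` data.frame (factor, marginal, unique),
#'   `joint` adjusted R-squared.
#' @export
variance_partition <- function(logmat, factors) {
  X <- scale(logmat)
  X <- X[, apply(X, 2, function(v) all(is.finite(v))), drop = FALSE]
  fac <- as.data.frame(factors)
  marginal <- unique_fr <- numeric(ncol(fac))
  adj <- function(rhs) {
    fm <- stats::as.formula(paste("X ~", rhs))  # env carries X and fac
    # vegan reports aliased terms (e.g. region-confounded sampling month);
    # expected here, not actionable
    suppressMessages(suppressWarnings(
      vegan::RsquareAdj(vegan::rda(fm, data = fac))$adj.r.squared))
  }
  joint <- adj(paste(names(fac), collapse = "+"))
  for (i in seq_along(fac)) {
    v <- fac[[i]]
    if (length(unique(v[!is.na(v)])) < 2) {
      marginal[i] <- 0; unique_fr[i] <- 0; next
    }
    marginal[i] <- adj(names(fac)[i])
    others <- setdiff(names(fac), names(fac)[i])
    without <- if (length(others)) adj(paste(others, collapse = "+")) else 0
    unique_fr[i] <- joint - without
  }
  list(per_factor = data.frame(factor = names(fac), marginal = marginal,
                               unique = unique_fr, stringsAsFactors = FALSE),
       joint = joint)
}

#' Principal component analysis of the exposure matrix
#'
#' Column-standardized log10 concentrations decomposed by
#' [stats::prcomp()]. Zero-variance columns are dropped with a warning.
#'
#' @param logmat subjects x chemicals matrix of log10 concentrations,
#'   no missing cells (impute first).
#' @param scale standardize columns (default TRUE).
#' @return list: scores, loadings (orthonormal), explained (variance
#'   fractions summing to 1), dropped (column names).
#' @export
pca_scores <- function(logmat, scale = TRUE) {
  v <- apply(logmat, 2, stats::var)
  dropped <- colnames(logmat)[!is.finite(v) | v == 0]
  if (length(dropped))
    warning(sprintf("dropping %d zero-variance column(s)", length(dropped)))
  keep <- setdiff(colnames(logmat), dropped)
  p <- stats::prcomp(logmat[, keep, drop = FALSE], center = TRUE, scale. = scale)
  list(scores = p$x, loadings = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2), dropped = dropped)
}
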