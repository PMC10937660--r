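#' Quantize exposures into ordinal quartile scores
#'
#' Per chemical, empirical quartile cut points (type-7 quantiles at 25/50/75
#' percent) map concentrations to scores 0--3. Ties on a cut point go to the
#' lower class; an all-tied column scores 0 everywhere. Cut points are
#' stored so new data can be scored on the same scale. Scores are invariant
#' to monotone transforms of the values.
#'
#' @param mat subjects x chemicals matrix (imputed concentrations, or their
#'   logs -- the scores are identical).
#' @param q number of classes (default 4 = quartiles).
#' @param cuts optional previously stored cut points to reuse.
#' @return list of class `quantized_exposures`: `scores` (integer matrix),
#'   `cuts` (list per chemical), `q`.
#' @export
quantize <- function(mat, q = 4, cuts = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < q) stop_input("need n >= q to form %d quantile classes", q)
  chems <- colnames(mat)
  if (is.null(cuts)) {
    cuts <- lapply(chems, function(ch)
      unname(stats::quantile(mat[, ch], probs = seq_len(q - 1) / q,
                             na.rm = TRUE, type = 7)))
    names(cuts) <- chems
  }
  scores <- vapply(chems, function(ch)
    findInterval(mat[, ch], cuts[[ch]], left.open = TRUE), integer(nrow(mat)))
  dimnames(scores) <- dimnames(mat)
  structure(list(scores = scores, cuts = cuts, q = q),
            class = "quantized_exposures")
}

# Softmax onto the weight simplex.
softmax <- function(theta) {
  e <- exp(theta - max(theta))
  e / sum(e)
}

# Negative log-likelihood of the logistic index model for a given simplex
# parameterisation; the index coefficient and covariate effects are profiled
# out by an inner IRLS fit. A quadratic penalty keeps the index coefficient
# on the requested side.
wqs_objective <- function(theta, Q, y, C, dir) {
  w <- softmax(theta)
  z <- drop(Q %*% w)
  X <- cbind(1, z, C)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  dev <- fit$deviance
  beta_z <- fit$coefficients[2]
  if (!is.finite(dev)) return(1e10)
  dev + 1e4 * max(0, -dir * beta_z)^2
}

#' Weighted quantile sum (WQS) regression
#'
#' Estimates a direction-constrained mixture index: non-negative per-chemical
#' weights on the quartile scores, summing to 1, chosen to maximise the
#' logistic-likelihood association between the weighted index and a binary
#' outcome. Weights are estimated on bootstrap resamples of a training split
#' and aggregated (by default weighted by each bootstrap's squared index
#' z-statistic, switchable to a plain mean); the final index is refit on the
#' held-out validation split with covariates. The confidence interval is
#' reported both on the odds-ratio scale (OR +/- 1.96 x SE(OR), the
#' convention this pipeline mirrors) and conventionally as
#' exp(beta +/- 1.96 x se).
#'
#' @param quantized a [quantize()] object (or integer score matrix).
#' @param y binary outcome (0/1), length = rows of the score matrix.
#' @param covariates optional data.frame of covariates.
#' @param direction "positive" or "negative" mixture effect.
#' @param n_boot bootstrap resamples (default 1000).
#' @param split training fraction (default 0.4; validation gets the rest).
#' @param seed integer seed controlling the split and the resamples.
#' @param weight_agg "signal" (z^2-weighted mean over bootstraps) or "mean".
#' @return list of class `mixture_result`: model = "wqs", direction, beta,
#'   se, or, ci (both forms), weights, n_boot, n_nonconverged, seed.
#' @export
fit_wqs <- function(quantized, y, covariates = NULL,
                    direction = c("positive", "negative"),
                    n_boot = 1000, split = 0.4, seed = 1L,
                    weight_agg = c("signal", "mean")) {
  direction <- match.arg(direction)
  weight_agg <- match.arg(weight_agg)
  Q <- if (inherits(quantized, "quantized_exposures")) quantized$scores else as.matrix(quantized)
  if (ncol(Q) < 1) stop_input("WQS needs >= 1 chemical")
  # a single-chemical index degenerates to logistic regression on its score
  y <- as.integer(y)
  stopifnot(all(y %in% c(0, 1)), length(y) == nrow(Q))
  dir <- if (direction == "positive") 1 else -1
  C <- covariate_matrix(covariates, nrow(Q))

  set.seed(seed)
  n <- nrow(Q)
  train <- sort(sample.int(n, max(2, round(split * n))))
  valid <- setdiff(seq_len(n), train)
  K <- ncol(Q)

  W <- matrix(NA_real_, n_boot, K)
  zstat <- numeric(n_boot)
  nonconv <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample(train, length(train), replace = TRUE)
    Qb <- Q[idx, , drop = FALSE]; yb <- y[idx]
    Cb <- if (is.null(C)) NULL else C[idx, , drop = FALSE]
    opt <- tryCatch(
      stats::optim(rep(0, K), wqs_objective, Q = Qb, y = yb, C = Cb,
                   dir = dir, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt)) { nonconv <- nonconv + 1L; next }
    w <- softmax(opt$par)
    W[b, ] <- w
    zb <- index_fit(Q[idx, , drop = FALSE] %*% w, yb, Cb)
    zstat[b] <- if (is.na(zb["se"]) || zb["se"] == 0) 0 else
      max(0, dir * zb["beta"] / zb["se"])
    if (opt$convergence != 0) nonconv <- nonconv + 1L
  }
  ok <- !is.na(W[, 1])
  if (sum(ok) < n_boot / 2)
    warning("unstable WQS fit: more than half of the bootstraps failed")
  W <- W[ok, , drop = FALSE]; zs <- zstat[ok]
  agg_w <- if (weight_agg == "signal" && sum(zs^2) > 0) zs^2 else rep(1, nrow(W))
  weights <- colSums(W * agg_w) / sum(agg_w)
  weights <- weights / sum(weights)
  names(weights) <- colnames(Q)

  zv <- drop(Q[valid, , drop = FALSE] %*% weights)
  Cv <- if (is.null(C)) NULL else C[valid, , drop = FALSE]
  fin <- index_fit(zv, y[valid], Cv)
  beta <- unname(fin["beta"]); se <- unname(fin["se"])
  or <- exp(beta)
  se_or <- or * se  # delta method on the OR scale
  structure(list(
    model = "wqs", direction = direction, beta = beta, se = se, or = or,
    p = unname(fin["p"]),
    ci_or_scale = c(low = or - 1.96 * se_or, high = or + 1.96 * se_or),
    ci_conventional = c(low = exp(beta - 1.96 * se), high = exp(beta + 1.96 * se)),
    weights = weights, n_boot = n_boot, n_nonconverged = nonconv,
    n_train = length(train), n_valid = length(valid), seed = seed),
    class = "mixture_result")
}

# Logistic fit of y on a fixed index + covariates; returns beta, se, p for
# the index term.
index_fit <- function(z, y, C) {
  X <- cbind(1, z = z, C)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  cf <- fit$coefficients
  # Wald se from the IRLS weights at convergence
  XtWX <- crossprod(X * sqrt(fit$weights))
  V <- tryCatch(solve(XtWX), error = function(e) matrix(NA, ncol(X), ncol(X)))
  se <- sqrt(V[2, 2])
  zval <- cf[2] / se
  c(beta = unname(cf[2]), se = unname(se),
    p = 2 * stats::pnorm(-abs(zval)))
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cf <- encode_covariates(as.data.frame(covariates))
  mm <- stats::model.matrix(~ ., data = cf)[, -1, drop = FALSE]
  stopifnot(nrow(mm) == n)
  mm
}

#' Quantile g-computation
#'
#' Generalized linear fit of the outcome on all quantized chemicals plus
#' covariates in one run. The joint effect psi is the sum of the
#' per-chemical coefficients -- the effect of raising every chemical one
#' quantile simultaneously -- with a delta-method standard error. Positive
#' weights are the positive coefficients normalized among positives,
#' negative weights likewise, so chemicals may pull in both directions in a
#' single model.
#'
#' @param quantized a [quantize()] object (or integer score matrix).
#' @param y outcome: binary (logistic link) or continuous (identity).
#' @param covariates optional data.frame of covariates.
#' @param ridge small L2 penalty applied only if the design is collinear.
#' @return list of class `mixture_result`: model = "qgcomp", psi, se, or,
#'   ci (both forms), weights_positive, weights_negative, coefficients.
#' @export
fit_qgcomp <- function(quantized, y, covariates = NULL, ridge = 1e-8) {
  Q <- if (inherits(quantized, "quantized_exposures")) quantized$scores else as.matrix(quantized)
  if (ncol(Q) < 2) stop_input("quantile g-computation needs >= 2 chemicals")
  C <- covariate_matrix(covariates, nrow(Q))
  binary <- all(y %in% c(0, 1, TRUE, FALSE))
  fam <- if (binary) stats::binomial() else stats::gaussian()
  X <- cbind(`(Intercept)` = 1, Q, C)
  fit <- suppressWarnings(stats::glm.fit(X, as.numeric(y), family = fam))
  cf <- fit$coefficients
  wts <- fit$weights
  if (any(is.na(cf))) {
    warning("collinear quantized design: ridge-stabilized fit")
    rf <- irls_ridge(X, as.numeric(y), fam, lambda = max(ridge, 1e-6))
    cf <- rf$coefficients
    wts <- rf$weights
  }
  XtWX <- crossprod(X * sqrt(wts)) + diag(ridge, ncol(X))
  V <- solve(XtWX)
  chem_idx <- 1 + seq_len(ncol(Q))
  bj <- cf[chem_idx]
  psi <- sum(bj)
  se <- sqrt(sum(V[chem_idx, chem_idx]))
  pos <- bj[bj > 0]; neg <- bj[bj < 0]
  wpos <- if (length(pos)) pos / sum(pos) else numeric(0)
  wneg <- if (length(neg)) neg / sum(neg) else numeric(0)
  or <- exp(psi); se_or <- or * se
  structure(list(
    model = "qgcomp", direction = "joint", psi = psi, beta = psi, se = se,
    or = or, p = 2 * stats::pnorm(-abs(psi / se)),
    ci_or_scale = c(low = or - 1.96 * se_or, high = or + 1.96 * se_or),
    ci_conventional = c(low = exp(psi - 1.96 * se), high = exp(psi + 1.96 * se)),
    coefficients = bj, weights_positive = wpos, weights_negative = wneg,
    family = fam$family),
    class = "mixture_result")
}

# L2-penalized IRLS for rank-deficient designs (intercept unpenalized).
irls_ridge <- function(X, y, fam, lambda = 1e-6, maxit = 50) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    w <- as.vector(fam$mu.eta(eta)^2 / fam$variance(mu))
    z <- eta + (y - mu) / fam$mu.eta(eta)
    new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X * w, z))
    if (max(abs(new - beta)) < 1e-10) { beta <- drop(new); break }
    beta <- drop(new)
  }
  eta <- drop(X %*% beta)
  mu <- fam$linkinv(eta)
  list(coefficients = stats::setNames(beta, colnames(X)),
       weights = as.vector(fam$mu.eta(eta)^2 / fam$variance(mu)))
}

#' Bayesian kernel machine regression placeholder
#'
#' Nonparametric kernel mixture modelling is outside this pipeline's scope;
#' the interface exists so pipeline configurations can name it and receive a
#' structured refusal.
#' @param ... ignored.
#' @export
fit_bkmr <- function(...) {
  stop_input("BKMR is not supported by this pipeline; use fit_wqs() or fit_qgcomp()")
}
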