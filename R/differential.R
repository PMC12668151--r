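# Differential module: offset log transform, lowess variance-trend weights,
# ordinal age encoding, consensus block (culture) correlation, per-peak
# generalized least squares, empirical-Bayes variance moderation, contrasts,
# and BH FDR.

#' Offset log transform of a normalized depth matrix
#'
#' `y = log(offset + x)` (natural log; effects are converted to log2 per
#' ordinal step downstream). Also returns the per-peak means and variances
#' that feed the variance-trend fit.
#'
#' @param norm_matrix peaks x samples matrix of non-negative values.
#' @param offset additive offset (default 0.1).
#' @return list with `y` (log matrix), `mu` and `v` (per-peak mean and
#'   variance), `offset`.
#' @export
log_transform <- function(norm_matrix, offset = 0.1) {
  m <- as.matrix(norm_matrix)
  if (any(m < 0, na.rm = TRUE)) stopf("negative values in norm matrix")
  y <- log(offset + m)
  mu <- rowMeans(y)
  v <- apply(y, 1L, var)
  list(y = y, mu = mu, v = v, offset = offset)
}

#' Inverse variance-trend weights from a lowess fit
#'
#' Fits the peak-wise variances against the peak-wise means with a locally
#' weighted (lowess) regression and returns per-peak weights equal to the
#' reciprocal of the fitted trend (floored at a small positive constant).
#' Fitting the trend rather than the raw per-peak variance avoids circular
#' weighting against the residual variance being moderated.
#'
#' @param mu,v per-peak means and variances (>= 10 peaks).
#' @param span lowess span (default 0.5).
#' @param floor lower bound on the fitted variance (default 1e-6).
#' @return list with `weights` and `trend` (fitted variance per peak).
#' @export
variance_trend_weights <- function(mu, v, span = 0.5, floor = 1e-6) {
  if (length(mu) < 10L) stopf("need at least 10 peaks for the variance trend")
  fit <- lowess(mu, v, f = span)
  trend <- approx(fit$x, fit$y, xout = mu, rule = 2, ties = "ordered")$y
  trend <- pmax(trend, floor)
  list(weights = 1 / trend, trend = trend)
}

#' Ordinal encoding of donor ages
#'
#' Distinct ages sorted ascending map to ranks 1..K; equal ages share a
#' rank, so replicates inherit their culture's rank. The rank is used as a
#' continuous predictor.
#'
#' @param ages integer ages, one per sample.
#' @return integer vector of ordinal ranks.
#' @export
encode_ordinal_age <- function(ages) {
  u <- sort(unique(ages))
  if (length(u) < 2L) stopf("need at least 2 distinct ages")
  match(ages, u)
}

#' Consensus intra-block (culture) correlation
#'
#' Estimates, per peak, the intra-class correlation of residuals after the
#' fixed-effect fit using the between/within block mean squares (an ANOVA
#' variance-component estimator, unbiased under the null), then combines the
#' per-peak estimates into a single consensus via a 10% trimmed mean on the
#' Fisher z scale, clipped to (-0.99, 0.99).
#'
#' @param y peaks x samples matrix (log scale).
#' @param design samples x coefficients design matrix.
#' @param blocks culture id per sample; at least 2 blocks need >= 2 members.
#' @param trim trim fraction for the Fisher-z consensus (default 0.1).
#' @return the consensus correlation (scalar).
#' @export
estimate_block_correlation <- function(y, design, blocks, trim = 0.10) {
  y <- as.matrix(y)
  X <- as.matrix(design)
  n <- ncol(y)
  p <- ncol(X)
  tab <- table(blocks)
  use_blocks <- names(tab)[tab >= 2L]
  if (length(use_blocks) < 2L) {
    stopf("need at least 2 blocks with >= 2 members")
  }
  H <- X %*% solve(crossprod(X), t(X))
  E <- y - y %*% t(H)                      # OLS residuals, peaks x samples
  sel <- blocks %in% use_blocks
  Es <- E[, sel, drop = FALSE]
  b <- blocks[sel]
  nb <- table(b)[unique(b)]
  B <- length(nb)
  N <- sum(nb)
  # membership matrix for block means
  M <- vapply(names(nb), function(g) as.numeric(b == g), numeric(length(b)))
  means <- (Es %*% M) / matrix(as.numeric(nb), nrow(Es), B, byrow = TRUE)
  ssb <- rowSums(sweep(means^2, 2L, as.numeric(nb), `*`))
  ssw <- rowSums(Es^2) - ssb
  # the fixed effects absorb their between-block rank from the between space
  Xb <- (t(M) %*% X[sel, , drop = FALSE]) / as.numeric(nb)
  p_b <- qr(Xb)$rank
  dfb <- B - p_b
  dfw <- N - B - (p - p_b)
  if (dfb < 1L || dfw < 1L) stopf("not enough degrees of freedom for blocks")
  msb <- ssb / dfb
  msw <- ssw / dfw
  n0 <- (N - sum(as.numeric(nb)^2) / N) / (B - 1)
  sig_b <- (msb - msw) / n0
  denom <- sig_b + msw
  rho <- ifelse(denom > 0, sig_b / denom, 0)
  rho[msw == 0 & msb > 0] <- 0.999
  rho <- pmin(pmax(rho, -0.999), 0.999)
  consensus <- tanh(mean(atanh(rho), trim = trim))
  min(max(consensus, -0.99), 0.99)
}

#' Per-peak generalized least squares with block correlation
#'
#' Fits each peak's profile against the design by GLS with within-block
#' covariance proportional to `(1 - rho) I + rho J` and an optional scalar
#' per-peak weight (from the variance trend); `rho = 0` reduces to weighted
#' least squares. The per-peak weight standardizes the residual variances so
#' they are comparable across peaks for moderation.
#'
#' @param y peaks x samples matrix.
#' @param design samples x coefficients matrix (full column rank).
#' @param weights per-peak scalar weights (default all 1).
#' @param rho consensus block correlation.
#' @param blocks culture id per sample (required when `rho != 0`).
#' @return a `g4_fit` list: `coefficients` (peaks x p), `sigma2`
#'   (standardized residual variance), `df_residual`, `cov_unscaled`
#'   (p x p, before the per-peak weight), `weights`, `design`.
#' @export
fit_weighted <- function(y, design, weights = NULL, rho = 0, blocks = NULL) {
  y <- as.matrix(y)
  X <- as.matrix(design)
  n <- ncol(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stopf("design matrix is rank deficient")
  if (n - p < 1L) stopf("no residual degrees of freedom")
  if (is.null(weights)) weights <- rep(1, nrow(y))
  if (any(weights <= 0)) stopf("weights must be positive")
  if (rho != 0) {
    if (is.null(blocks)) stopf("blocks required when rho != 0")
    Sigma <- diag(n)
    for (g in unique(blocks)) {
      idx <- which(blocks == g)
      Sigma[idx, idx] <- rho
    }
    diag(Sigma) <- 1
    Wh <- solve(t(chol(Sigma)))              # whitening matrix
    Xw <- Wh %*% X
    Yw <- y %*% t(Wh)
  } else {
    Xw <- X
    Yw <- y
  }
  XtXi <- solve(crossprod(Xw))
  B <- Yw %*% Xw %*% XtXi                    # peaks x p
  E <- Yw - B %*% t(Xw)
  df <- n - p
  sigma2 <- weights * rowSums(E^2) / df
  dimnames(B) <- list(rownames(y), colnames(X))
  structure(list(coefficients = B, sigma2 = sigma2, df_residual = df,
                 cov_unscaled = XtXi, weights = weights, design = X),
            class = "g4_fit")
}

# Newton solve of trigamma(x) = y  (y > 0), vectorized
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-peak variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` by
#' moment matching on `log(s^2)` (digamma/trigamma method), squeezes each
#' residual variance towards the prior,
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and returns moderated t
#' statistics with `d0 + d` degrees of freedom. Zero spread of the observed
#' variances forces `d0 = Inf` (all `s~^2 = s0^2`, normal reference).
#'
#' @param fit a `g4_fit` from [fit_weighted()] (or [fit_contrasts()]).
#' @param coef column of the coefficient matrix to test.
#' @return list with `table` (data frame `estimate`, `t`, `p_value`, `fdr`,
#'   `s2_post` per peak), `d0`, `s0_2`.
#' @export
ebayes_moderate <- function(fit, coef = 2L) {
  s2 <- fit$sigma2
  d <- fit$df_residual
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stopf("all residual variances are zero; cannot moderate")
  if (sum(ok) < 10L) stopf("need at least 10 peaks with positive variance")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  nn <- length(e)
  evar <- sum((e - emean)^2) / (nn - 1)
  rhs <- evar - trigamma(d / 2)
  if (rhs <= 0 || !is.finite(rhs)) {
    # zero excess spread: infinite prior df; with the variance known the
    # natural estimate is the arithmetic mean (unbiased for sigma^2), so
    # constant variances stay fixed
    d0 <- Inf
    s0_2 <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_all <- ifelse(ok, s2, 0)
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_2 + d * s2_all) / (d0 + d)
    df_total <- d0 + d
  }
  est <- fit$coefficients[, coef]
  u <- if (!is.null(fit$stdev_unscaled)) {
    fit$stdev_unscaled[, coef]
  } else {
    sqrt(fit$cov_unscaled[coef, coef] / fit$weights)
  }
  t_mod <- est / (sqrt(s2_post) * u)
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod))
       else 2 * pt(-abs(t_mod), df = df_total)
  list(table = data.frame(estimate = est, t = t_mod, p_value = p,
                          fdr = bh_fdr(p), s2_post = s2_post,
                          row.names = rownames(fit$coefficients)),
       d0 = d0, s0_2 = s0_2)
}

#' Contrast estimates from a fitted model
#'
#' Computes `c' beta` and its unscaled standard deviation
#' `sqrt(c' (X'WX)^-1 c)` for each contrast column; the result can be passed
#' to [ebayes_moderate()]. Supports group contrasts over culture-indicator
#' designs (e.g. mean of old cultures minus mean of young).
#'
#' @param fit a `g4_fit`.
#' @param contrasts numeric vector or p x k matrix of contrast columns.
#' @return a `g4_fit` whose coefficient columns are the contrast estimates.
#' @export
fit_contrasts <- function(fit, contrasts) {
  C <- as.matrix(contrasts)
  p <- ncol(fit$coefficients)
  if (nrow(C) != p) stopf("contrast length %d != number of coefficients %d",
                          nrow(C), p)
  if (any(colSums(abs(C)) == 0)) stopf("zero contrast vector")
  est <- fit$coefficients %*% C
  u0 <- sqrt(diag(t(C) %*% fit$cov_unscaled %*% C))     # per contrast
  su <- outer(1 / sqrt(fit$weights), u0)
  out <- fit
  out$coefficients <- est
  out$stdev_unscaled <- su
  out
}

#' Benjamini-Hochberg adjusted p-values
#' @param p p-values in `[0, 1]`.
#' @return BH step-up adjusted values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Ordinal-age differential analysis of a normalized coverage matrix
#'
#' The full regression pipeline for one assay: offset log transform, lowess
#' variance-trend weights, consensus culture correlation, per-peak GLS
#' against intercept + ordinal age, and empirical-Bayes moderation. The
#' reported `logFC` is the log2 change per ordinal-age step (the natural-log
#' slope divided by `log(2)`).
#'
#' @param norm_matrix peaks x samples matrix of normalized depth.
#' @param samples a [sample_sheet()] matching the columns.
#' @param offset log-transform offset (default 0.1).
#' @param span lowess span for the variance trend.
#' @param use_weights apply inverse variance-trend weights (default `TRUE`).
#' @param block_correlation estimate and use the consensus culture
#'   correlation (default `TRUE`; requires replicated cultures).
#' @return list with `table` (data frame `peak_id`, `logFC`, `t`,
#'   `p_value`, `fdr`), `d0`, `s0_2`, `rho`, `ordinal_map`, `fit`.
#' @export
age_regression <- function(norm_matrix, samples, offset = 0.1, span = 0.5,
                           use_weights = TRUE, block_correlation = TRUE) {
  stopifnot(identical(colnames(norm_matrix), samples$sample_id))
  lt <- log_transform(norm_matrix, offset)
  ordinal <- encode_ordinal_age(samples$age_years)
  X <- cbind(intercept = 1, ordinal = ordinal)
  w <- if (use_weights) variance_trend_weights(lt$mu, lt$v, span)$weights
       else NULL
  rho <- 0
  replicated <- any(table(samples$culture_id) >= 2L)
  if (block_correlation && replicated) {
    rho <- estimate_block_correlation(lt$y, X, samples$culture_id)
  }
  fit <- fit_weighted(lt$y, X, weights = w, rho = rho,
                      blocks = samples$culture_id)
  eb <- ebayes_moderate(fit, coef = 2L)
  u <- sort(unique(samples$age_years))
  list(table = data.frame(peak_id = rownames(norm_matrix),
                          logFC = eb$table$estimate / log(2),
                          t = eb$table$t, p_value = eb$table$p_value,
                          fdr = eb$table$fdr, stringsAsFactors = FALSE),
       d0 = eb$d0, s0_2 = eb$s0_2, rho = rho,
       ordinal_map = setNames(seq_along(u), u), fit = fit)
}
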