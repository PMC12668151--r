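test_that("offset log transform and summaries behave", {
  m <- matrix(c(0, 0.9, 3, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  lt <- log_transform(m)
  expect_equal(lt$y["a", "s1"], log(0.1))
  expect_equal(lt$y["a", "s2"], 0)
  expect_equal(lt$v[["b"]], 0)           # constant row
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("variance-trend weights track the mean-variance relation", {
  set.seed(61)
  mu <- runif(200, 0, 10)
  v_flat <- rep(0.5, 200) + rnorm(200, 0, 1e-6)
  w <- variance_trend_weights(mu, v_flat)
  expect_true(all(abs(w$weights - 2) < 0.02))
  v_inc <- 0.1 + 0.2 * mu
  w2 <- variance_trend_weights(mu, v_inc)
  expect_lt(cor(mu, w2$weights, method = "spearman"), 0)
  w3 <- variance_trend_weights(mu, v_inc)
  expect_identical(w2$weights, w3$weights)  # lowess is deterministic
  expect_error(variance_trend_weights(1:5, 1:5), "at least 10")
})

test_that("ordinal age encoding maps sorted distinct ages to ranks", {
  expect_equal(encode_ordinal_age(c(22, 24, 32, 34, 53, 56, 72, 73)), 1:8)
  expect_equal(encode_ordinal_age(c(30, 30, 40)), c(1L, 1L, 2L))
  expect_equal(encode_ordinal_age(c(40, 30)), c(2L, 1L))
  expect_error(encode_ordinal_age(c(30, 30)), "distinct")
})

test_that("consensus block correlation hits its limits and recovers truth", {
  samples <- default_sample_sheet()
  X <- cbind(1, encode_ordinal_age(samples$age_years))
  blocks <- samples$culture_id
  # exact duplicates within blocks: clipped at 0.99
  set.seed(71)
  base <- matrix(rnorm(200 * 8), 200, 8)
  ydup <- base[, match(blocks, unique(blocks))] +
    matrix(rnorm(200 * 16, 0, 1e-8), 200, 16)
  expect_gt(estimate_block_correlation(ydup, X, blocks), 0.95)
  # independent noise: consensus near zero
  y0 <- matrix(rnorm(5000 * 16), 5000, 16)
  expect_lt(abs(estimate_block_correlation(y0, X, blocks)), 0.05)
  # planted intra-class correlation 0.5 recovered within 0.1
  u <- matrix(rnorm(5000 * 8), 5000, 8)
  y5 <- u[, match(blocks, unique(blocks))] * sqrt(0.5) +
    matrix(rnorm(5000 * 16), 5000, 16) * sqrt(0.5)
  rho <- estimate_block_correlation(y5, X, blocks)
  expect_gt(rho, 0.4)
  expect_lt(rho, 0.6)
  expect_error(estimate_block_correlation(y0, X, seq_len(16)), "blocks")
})

test_that("weighted fits interpolate exact data and match OLS closed form", {
  samples <- default_sample_sheet()
  ordinal <- encode_ordinal_age(samples$age_years)
  X <- cbind(intercept = 1, ordinal = ordinal)
  y <- matrix(2 + 0.5 * ordinal, 1, 16)
  f <- fit_weighted(y, X)
  expect_equal(unname(f$coefficients[1, ]), c(2, 0.5))
  expect_equal(f$sigma2[1], 0)
  # doubling the weights leaves coefficients unchanged
  y2 <- matrix(rnorm(10 * 16), 10, 16)
  fa <- fit_weighted(y2, X, weights = rep(1, 10))
  fb <- fit_weighted(y2, X, weights = rep(2, 10))
  expect_equal(fa$coefficients, fb$coefficients)
  # normal-equations oracle on 100 random small problems
  set.seed(81)
  for (i in 1:100) {
    n <- sample(6:12, 1)
    Xi <- cbind(1, rnorm(n), rnorm(n))
    yi <- matrix(rnorm(n), 1, n)
    fi <- fit_weighted(yi, Xi)
    beta_oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% t(yi))
    expect_equal(unname(fi$coefficients[1, ]), unname(drop(beta_oracle)),
                 tolerance = 1e-10)
  }
  # GLS with rho = 0 is identical to the plain weighted fit
  fg <- fit_weighted(y2, X, rho = 0, blocks = samples$culture_id)
  expect_identical(fg$coefficients, fa$coefficients)
  expect_error(fit_weighted(y2, cbind(1, ordinal, ordinal)), "rank deficient")
})

test_that("GLS under block correlation widens the ordinal-age standard error", {
  samples <- default_sample_sheet()
  ordinal <- encode_ordinal_age(samples$age_years)
  X <- cbind(1, ordinal)
  set.seed(82)
  y <- matrix(rnorm(50 * 16), 50, 16)
  f0 <- fit_weighted(y, X)
  f5 <- fit_weighted(y, X, rho = 0.5, blocks = samples$culture_id)
  # the age predictor is block-constant, so positive correlation inflates
  # its sampling variance relative to independence
  u0 <- sqrt(f0$cov_unscaled[2, 2])
  u5 <- sqrt(f5$cov_unscaled[2, 2])
  expect_gt(u5, u0)
})

test_that("empirical-Bayes moderation matches limma and recovers planted
           hyperparameters", {
  skip_if_not_installed("limma")
  # heteroscedastic rows give a finite prior df
  set.seed(91)
  sd_row <- exp(rnorm(2000, 0, 0.5))
  y <- matrix(rnorm(2000 * 10), 2000, 10) * sd_row
  X <- cbind(1, rep(0:1, each = 5))
  fit <- fit_weighted(y, X)
  eb <- ebayes_moderate(fit, coef = 2)
  lf <- limma::eBayes(limma::lmFit(y, X))
  expect_true(is.finite(eb$d0))
  expect_equal(eb$table$t, unname(lf$t[, 2]), tolerance = 1e-10)
  expect_equal(eb$table$p_value, unname(lf$p.value[, 2]), tolerance = 1e-10)
  expect_equal(eb$d0, lf$df.prior, tolerance = 1e-8)
  expect_equal(eb$s0_2, unname(lf$s2.prior), tolerance = 1e-8)
  # homoscedastic rows push the prior df towards infinity, where our
  # reference distribution is normal versus limma's pooled-df t; p-values
  # then agree only to that approximation
  yh <- matrix(rnorm(2000 * 10), 2000, 10)
  fh <- fit_weighted(yh, X)
  ebh <- ebayes_moderate(fh, coef = 2)
  lfh <- limma::eBayes(limma::lmFit(yh, X))
  expect_equal(ebh$table$p_value, unname(lfh$p.value[, 2]), tolerance = 1e-3)
  # moderated variance lies between the observed and prior variances
  lo <- pmin(fit$sigma2, eb$s0_2)
  hi <- pmax(fit$sigma2, eb$s0_2)
  expect_true(all(eb$table$s2_post >= lo - 1e-12 &
                  eb$table$s2_post <= hi + 1e-12))

  # identical variances force infinite prior df and leave t ordinary
  d <- 8
  fit2 <- fit
  fit2$sigma2 <- rep(2, 2000)
  fit2$df_residual <- d
  eb2 <- ebayes_moderate(fit2, coef = 2)
  expect_true(is.infinite(eb2$d0))
  expect_equal(eb2$table$s2_post, rep(2, 2000))

  # planted scaled-inverse-chi-squared prior (d0 = 4, s0^2 = 0.05)
  set.seed(92)
  npk <- 5000
  sig2 <- 4 * 0.05 / rchisq(npk, df = 4)
  s2 <- sig2 * rchisq(npk, df = 14) / 14
  fit3 <- structure(list(coefficients = matrix(0, npk, 2), sigma2 = s2,
                         df_residual = 14, cov_unscaled = diag(2),
                         weights = rep(1, npk)), class = "g4_fit")
  eb3 <- ebayes_moderate(fit3, coef = 2)
  expect_lt(abs(eb3$d0 - 4) / 4, 0.25)
  expect_lt(abs(eb3$s0_2 - 0.05) / 0.05, 0.25)
  fit4 <- fit3
  fit4$sigma2 <- rep(0, npk)
  expect_error(ebayes_moderate(fit4), "zero")
})

test_that("contrasts reproduce group-mean differences and the pooled t", {
  set.seed(101)
  n <- 10
  grp <- rep(0:1, each = n / 2)
  X <- cbind(g0 = 1 - grp, g1 = grp)      # culture-indicator style design
  y <- matrix(rnorm(50 * n), 50, n)
  fit <- fit_weighted(y, X)
  fc <- fit_contrasts(fit, c(-1, 1))
  dm <- rowMeans(y[, grp == 1]) - rowMeans(y[, grp == 0])
  expect_equal(unname(fc$coefficients[, 1]), dm)
  # before moderation the contrast t equals the pooled-variance t-test
  t_ours <- fc$coefficients[, 1] / (sqrt(fit$sigma2) * fc$stdev_unscaled[, 1])
  t_oracle <- apply(y, 1, function(r) {
    t.test(r[grp == 1], r[grp == 0], var.equal = TRUE)$statistic
  })
  expect_equal(unname(t_ours), unname(t_oracle), tolerance = 1e-10)
  expect_error(fit_contrasts(fit, c(0, 0)), "zero contrast")
  expect_error(fit_contrasts(fit, c(1, -1, 0)), "contrast length")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04)
  expect_true(all(diff(bh_fdr(sort(p))) >= 0))
  expect_error(bh_fdr(c(0.5, 1.5)), "outside")
})

test_that("the full age regression is calibrated under the null", {
  samples <- default_sample_sheet()
  gs <- simulate_genome(1, 60000, motifs_per_chrom = 2, seed = 111)
  pk <- simulate_peaks_and_transcripts(gs, n_genes = 0, n_peaks = 2000,
                                       motif_peak_fraction = 0,
                                       null_fraction = 1, seed = 112)
  cv <- simulate_coverage(pk$peaks_atac, samples, beta = 0, culture_sd = 0,
                          seed = 113)
  nm <- sweep(cv$counts, 2, normalization_factors(cv$background), `*`)
  ar <- age_regression(nm, samples)
  expect_lt(abs(mean(ar$table$p_value < 0.05) - 0.05), 0.015)
  expect_lt(abs(ar$rho), 0.1)
})
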