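test_that("PCA matches the covariance eigendecomposition", {
  set.seed(21)
  X <- matrix(rnorm(20 * 6), 20, 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.2))
  pc <- fit_pca(X)
  ev <- eigen(cov(X), symmetric = TRUE)
  expect_equal(pc$explained_variance_pct,
               100 * ev$values / sum(ev$values), tolerance = 1e-9)
  # full-rank scores + loadings reconstruct the centred data
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(pc$scores %*% t(pc$loadings), Xc, tolerance = 1e-9,
               ignore_attr = TRUE)
  # scores are uncorrelated
  cc <- cov(pc$scores); diag(cc) <- 0
  expect_lt(max(abs(cc)), 1e-9)
  # collinear data: one component carries everything
  line <- outer(rnorm(10), c(1, 2, 3))
  expect_equal(fit_pca(line)$explained_variance_pct[1], 100,
               tolerance = 1e-9)
  expect_warning(fit_pca(X, n_components = 50), "truncated")
})

test_that("LDA separates well-spaced Gaussian classes perfectly", {
  set.seed(31)
  n <- 30
  X <- rbind(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4, 10), n),
             matrix(rnorm(n * 4, 20), n))
  y <- rep(c("a", "b", "c"), each = n)
  res <- crossval_lda(X, y, n_folds = 3)
  expect_equal(res$prediction_pct, 100)
  expect_equal(res$recognition_pct, 100)
  expect_equal(unname(diag(res$confusion_cv)), rep(n, 3))
  expect_equal(sum(res$root_variance_pct), 100, tolerance = 1e-9)
  expect_error(crossval_lda(X[1:31, ], y[1:31], n_folds = 3), "at least")
})

test_that("LDA prediction sits at chance for permuted labels", {
  set.seed(32)
  X <- matrix(rnorm(60 * 5), 60)
  accs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    y <- sample(rep(c("a", "b", "c"), each = 20))
    crossval_lda(X, y, n_folds = 3, seed = s)$prediction_pct
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 100 / 3), 3 * se + 1e-9)
})

test_that("cross-validated accuracy does not beat resubstitution on average", {
  set.seed(33)
  gaps <- vapply(1:20, function(s) {
    set.seed(s)
    X <- rbind(matrix(rnorm(12 * 4), 12), matrix(rnorm(12 * 4, 1.2), 12))
    y <- rep(c("a", "b"), each = 12)
    r <- crossval_lda(X, y, n_folds = 3, seed = s)
    r$recognition_pct - r$prediction_pct
  }, numeric(1))
  expect_gte(mean(gaps), 0)
})

test_that("wide blocks are PCA-compressed without leaking held-out rows", {
  set.seed(34)
  X <- cbind(matrix(rnorm(30 * 50), 30),
             rep(c(0, 5, 10), each = 10) + rnorm(30, sd = 0.1))
  y <- rep(c("a", "b", "c"), each = 10)
  res <- crossval_lda(X, y, n_folds = 3)
  expect_equal(res$prediction_pct, 100)
})

test_that("NIPALS extracts an exact one-component model and fixes signs", {
  set.seed(41)
  # rank-one predictors: a single latent variable carries everything
  t1 <- rnorm(30)
  X <- outer(t1, c(1, -2, 0.5, 0.2, 3))
  y <- 2.5 * t1
  fit <- fit_plsr_nipals(X, y, n_latent = 1)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
  expect_gt(fit$W[which.max(abs(fit$W[, 1])), 1], 0)
  X <- matrix(rnorm(30 * 5), 30)
  # response orthogonal to X: coefficients collapse to zero
  Xo <- qr.Q(qr(cbind(1, X)))
  yo <- rnorm(30)
  yo <- yo - Xo %*% crossprod(Xo, yo)
  fit0 <- fit_plsr_nipals(X, drop(yo), n_latent = 3)
  m <- regression_metrics(drop(yo), predict(fit0, X), predict(fit0, X))
  expect_lt(abs(m$r2_tr), 1e-6)
  expect_error(fit_plsr_nipals(X, y, n_latent = 40), "exceeds")
})

test_that("full-rank NIPALS equals ordinary least squares", {
  set.seed(42)
  X <- matrix(rnorm(40 * 6), 40)
  y <- drop(X %*% rnorm(6)) + rnorm(40)
  fit <- fit_plsr_nipals(X, y, n_latent = 6)
  ols <- lm(y ~ X)
  expect_equal(predict(fit, X), unname(fitted(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$coefs[, 6]), unname(coef(ols)[-1]),
               tolerance = 1e-8)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  set.seed(43)
  X <- matrix(rnorm(25 * 8), 25,
              dimnames = list(NULL, paste0("x", 1:8)))
  y <- drop(X %*% c(1, -1, 2, rep(0, 5))) + rnorm(25, sd = 0.3)
  fit <- fit_plsr_nipals(X, y, n_latent = 3, scale_x = TRUE)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                      scale = TRUE)
  pred_mo <- predict(mo, X)$predict[, 1, 3]
  expect_equal(predict(fit, X), unname(pred_mo), tolerance = 1e-6)
})

test_that("grouped CV selects latent variables by minimum RMSECV", {
  # noiseless linear response: one latent variable suffices
  toy <- toy_regression(n_units = 8, per_unit = 3, p = 4,
                        beta = c(3, 0, 0, 0), noise_sd = 0, seed = 51)
  cv <- crossval_plsr(toy$X, toy$y, toy$groups, max_latent = 4)
  expect_lt(cv$rmsecv, 1e-8)
  expect_equal(cv$r2_cv, 1, tolerance = 1e-9)
  # pure-noise response: negative CV R-squared is legal and unclipped
  set.seed(52)
  noise <- rnorm(length(toy$y))
  cvn <- crossval_plsr(toy$X, noise, toy$groups, max_latent = 4)
  expect_lt(cvn$r2_cv, 0.5)
  expect_true(is.finite(cvn$r2_cv))
  expect_error(crossval_plsr(toy$X, toy$y, rep("g", length(toy$y))),
               "full data")
})

test_that("grouped CV recovers the noise floor of a known model", {
  ratios <- vapply(1:10, function(s) {
    toy <- toy_regression(n_units = 15, per_unit = 5, p = 10,
                          noise_sd = 0.5, seed = 200 + s)
    cv <- crossval_plsr(toy$X, toy$y, toy$groups, max_latent = 6)
    cv$rmsecv / toy$noise_sd
  }, numeric(1))
  expect_true(all(abs(ratios - 1) < 0.2))
})

test_that("regression metrics follow their defining identities", {
  set.seed(61)
  y <- rnorm(40, 10, 3)
  m <- regression_metrics(y, y, y)
  expect_equal(m$r2_tr, 1); expect_equal(m$rmsec, 0)
  m2 <- regression_metrics(y, rep(mean(y), 40), rep(mean(y), 40))
  expect_equal(m2$r2_tr, 0)
  yhat <- y + rnorm(40)
  m3 <- regression_metrics(y, yhat, yhat)
  # RPD and R2cv are tied up to the n/(n-1) factor of SD vs RMSE
  n <- length(y)
  expect_equal(m3$rpd, sqrt(1 / (1 - m3$r2_cv)) * sqrt(n / (n - 1)),
               tolerance = 1e-12)
  expect_error(regression_metrics(rep(1, 5), rnorm(5), rnorm(5)),
               "zero variance")
})
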