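test_that("Savitzky-Golay leaves polynomials up to the fit order fixed", {
  wl <- seq(900, 1700, by = 10)
  quad <- toy_spectral(3, wl, f = function(w) {
    x <- (w - 1300) / 100; 3 + 2 * x + 0.5 * x^2
  })
  quad$X <- quad$X - (quad$X - t(vapply(1:3, function(i) {
    x <- (wl - 1300) / 100; 3 + 2 * x + 0.5 * x^2
  }, numeric(length(wl)))))  # strip the helper's noise: exact quadratic
  sm <- savgol_smooth(quad, window = 11, polyorder = 2)
  # truncated-window edge fitting keeps the quadratic exact everywhere
  expect_equal(sm$X, quad$X, tolerance = 1e-9)
  const <- quad; const$X[] <- 1.7
  expect_equal(savgol_smooth(const, 11, 2)$X, const$X, tolerance = 1e-12)
})

test_that("interior smoothing equals the reference Savitzky-Golay filter", {
  wl <- seq(1, 101, by = 1)
  set.seed(3)
  X <- matrix(rnorm(3 * length(wl)), 3)
  blk <- spectral_block(X, wl, data.frame(sample_id = "a", class = "a",
                                          replicate = 1:3))
  sm <- savgol_smooth(blk, window = 21, polyorder = 2)
  orc <- t(apply(X, 1, signal::sgolayfilt, p = 2, n = 21))
  interior <- 11:91
  expect_equal(sm$X[, interior], orc[, interior], tolerance = 1e-9)
})

test_that("Savitzky-Golay smoothing is linear and validates its window", {
  blk1 <- toy_spectral(4, seed = 5)
  blk2 <- toy_spectral(4, seed = 6)
  mix <- blk1; mix$X <- 2 * blk1$X - 3 * blk2$X
  expect_equal(savgol_smooth(mix, 15, 2)$X,
               2 * savgol_smooth(blk1, 15, 2)$X -
                 3 * savgol_smooth(blk2, 15, 2)$X,
               tolerance = 1e-9)
  expect_error(savgol_smooth(blk1, window = 10), "odd")
  expect_error(savgol_smooth(blk1, window = 3, polyorder = 3), "polyorder")
  expect_error(savgol_smooth(blk1, window = 999), "exceeds")
})

test_that("MSC inverts affine scatter and matches the regression oracle", {
  blk <- toy_spectral(5, seed = 2, f = function(w) 0.5 + 2e-3 * w +
                        0.3 * exp(-((w - 1400) / 80)^2))
  ref <- colMeans(blk$X)
  same <- blk; same$X <- matrix(ref, 3, length(ref), byrow = TRUE)
  same$meta <- same$meta[1:3, ]
  expect_equal(msc_correct(same, ref)$block$X, same$X, tolerance = 1e-9)
  scat <- blk; scat$X <- 2 * matrix(ref, nrow(blk$X), length(ref),
                                    byrow = TRUE) + 3
  expect_equal(scat$X[1, ] * 0 + msc_correct(scat, ref)$block$X[1, ],
               ref, tolerance = 1e-9, ignore_attr = TRUE)
  # normal-equations oracle per spectrum
  corr <- msc_correct(blk)$block$X
  for (i in seq_len(nrow(blk$X))) {
    fit <- lm(blk$X[i, ] ~ ref)
    expect_equal(corr[i, ],
                 (blk$X[i, ] - coef(fit)[1]) / coef(fit)[2],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # idempotent under a fixed reference
  once <- msc_correct(blk, ref)$block
  twice <- msc_correct(once, ref)$block
  expect_equal(twice$X, once$X, tolerance = 1e-9)
  flat <- rep(1, ncol(blk$X))
  expect_error(msc_correct(blk, flat), "constant reference")
})

test_that("wavelength truncation keeps the closed interval", {
  blk <- toy_spectral(3, seq(900, 1700, by = 3))
  tr <- truncate_range(blk, 950, 1650)
  expect_true(all(tr$wavelengths >= 950 & tr$wavelengths <= 1650))
  expect_equal(ncol(tr$X), length(tr$wavelengths))
  single <- truncate_range(blk, 900, 900)
  expect_equal(single$wavelengths, 900)
  expect_error(truncate_range(blk, 100, 200), "no wavelengths")
})

test_that("autoscaling standardizes training and transfers to held-out rows", {
  set.seed(4)
  train <- matrix(rnorm(60, mean = 5, sd = 3), 10)
  held <- matrix(rnorm(12, mean = 5, sd = 3), 2)
  sc <- autoscale_fit_apply(train, held)
  expect_true(all(abs(colMeans(sc$train)) < 1e-12))
  expect_equal(apply(sc$train, 2, sd), rep(1, 6), tolerance = 1e-12)
  expect_equal(autoscale_fit_apply(train, train)$applied, sc$train)
  mu <- colMeans(train); s <- apply(train, 2, sd)
  expect_equal(sc$applied, sweep(sweep(held, 2, mu), 2, s, `/`))
  cst <- train; cst[, 2] <- 7; colnames(cst) <- paste0("v", 1:6)
  expect_error(autoscale_fit_apply(cst), "v2")
})

test_that("session drift correction removes additive drift exactly", {
  set.seed(9)
  clean <- matrix(rnorm(40, 100, 5), 20, 2)
  sess <- rep(1:4, each = 5)
  drift <- matrix(rnorm(8, sd = 10), 4, 2)
  noisy <- clean + drift[sess, ]
  blk_clean <- toy_sensor(clean, classes = rep("A", 20), sessions = sess)
  blk_noisy <- toy_sensor(noisy, classes = rep("A", 20), sessions = sess)
  cc <- drift_correct_etongue(blk_clean)
  cn <- drift_correct_etongue(blk_noisy)
  # identical up to the per-sensor constant mean of the drift vectors
  expect_equal(sweep(cn$X, 2, colMeans(cn$X)),
               sweep(cc$X, 2, colMeans(cc$X)), tolerance = 1e-9)
  # grand means preserved; session means equalized
  expect_equal(colMeans(cn$X), colMeans(noisy), ignore_attr = TRUE)
  for (s in 1:4)
    expect_equal(colMeans(cn$X[sess == s, ]), colMeans(cn$X),
                 tolerance = 1e-9)
  # within-session contrasts untouched
  expect_equal(cn$X[2, ] - cn$X[4, ], noisy[2, ] - noisy[4, ],
               ignore_attr = TRUE)
  # no drift present: nothing changes
  expect_equal(drift_correct_etongue(blk_clean)$X -
                 (blk_clean$X - outer(rep(1, 20), rep(0, 2))),
               cc$X - blk_clean$X, tolerance = 1e-9)
  one <- toy_sensor(clean, classes = rep("A", 20), sessions = rep(1L, 20))
  expect_warning(out <- drift_correct_etongue(one), "single session")
  expect_equal(out$X, one$X)
})

test_that("discrimination power ranks sensors by the Fisher ratio", {
  set.seed(11)
  classes <- rep(c("A", "B", "C", "D", "E"), each = 6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  X[, 1] <- X[, 1] + 5 * as.integer(factor(classes))   # strong
  X[, 2] <- 3.14                                        # constant
  X[, 3] <- as.integer(factor(classes))                 # perfect separator
  blk <- toy_sensor(X, classes = classes)
  score <- discrimination_power(X, classes)
  expect_equal(score[[2]], 0)
  expect_equal(score[[3]], Inf)
  # one-way ANOVA SSB/SSW oracle for a stochastic sensor
  a <- anova(lm(X[, 1] ~ factor(classes)))
  expect_equal(score[[1]], a$`Sum Sq`[1] / a$`Sum Sq`[2], tolerance = 1e-9)
  sel <- select_sensors_by_discrimination(blk, k = 2)
  expect_equal(sel$sensor_ids, c("S1", "S3"))
  # affine rescaling of one sensor leaves its rank unchanged
  X2 <- X; X2[, 1] <- 100 * X2[, 1] - 7
  expect_equal(order(-discrimination_power(X2, classes)),
               order(-score))
  expect_error(discrimination_power(X, rep("A", 30)), "2 classes")
})
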