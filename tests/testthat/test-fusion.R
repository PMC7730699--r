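make_three_blocks <- function(seed = 1) {
  set.seed(seed)
  classes <- c("A", "B", "C", "D", "E")
  units <- expand.grid(replicate = 1:3, class = classes,
                       stringsAsFactors = FALSE)
  nir_meta <- units[rep(seq_len(nrow(units)), each = 5), ]
  nir_meta$sample_id <- nir_meta$class
  nir_meta$scan <- rep(1:5, nrow(units))
  wl <- seq(1000, 1090, by = 10)
  nir <- spectral_block(matrix(rnorm(nrow(nir_meta) * length(wl)),
                               nrow(nir_meta)), wl, nir_meta)
  et_meta <- units[rep(seq_len(nrow(units)), times = 4), ]
  et_meta$sample_id <- et_meta$class
  et_meta$session <- rep(1:4, each = nrow(units))
  et <- sensor_block(matrix(rnorm(nrow(et_meta) * 7), nrow(et_meta)),
                     paste0("T", 1:7), et_meta)
  en_meta <- units
  en_meta$sample_id <- en_meta$class
  en_meta$session <- 1L
  en <- sensor_block(matrix(rnorm(nrow(units) * 20), nrow(units)),
                     paste0("N", 1:20), en_meta)
  list(nir = nir, etongue = et, enose = en)
}

test_that("block alignment matches rows by preparation unit", {
  b <- make_three_blocks()
  fused <- align_blocks(b$nir, b$etongue, b$enose)
  expect_equal(nrow(fused$X), 75)
  expect_equal(ncol(fused$X), 10 + 7 + 20)
  expect_equal(as.vector(table(fused$block_map$block)[c("nir", "etongue",
                                                        "enose")]),
               c(10, 7, 20))
  # every e-nose row is replicated across its unit's five NIR scans
  raw <- sweep(sweep(fused$X, 2, fused$scaler$sd, `*`), 2,
               -fused$scaler$mean)
  en_cols <- fused$block_map$block == "enose"
  u <- paste(fused$meta$sample_id, fused$meta$replicate, sep = "/")
  for (g in unique(u)) {
    rows <- which(u == g)
    expect_equal(length(rows), 5)
    expect_equal(apply(raw[rows, en_cols], 2, var), rep(0, 20),
                 tolerance = 1e-18, ignore_attr = TRUE)
  }
  # NIR content is recoverable from the fused matrix (scaling undone)
  nir_cols <- fused$block_map$block == "nir"
  expect_equal(unname(raw[, nir_cols]), unname(b$nir$X), tolerance = 1e-9)
})

test_that("alignment degenerates to concatenation for matched single rows", {
  b <- make_three_blocks()
  one_scan <- b$nir
  keep <- b$nir$meta$scan == 1
  one_scan$X <- b$nir$X[keep, ]; one_scan$meta <- b$nir$meta[keep, ]
  one_et <- b$etongue
  keep_et <- b$etongue$meta$session == 1
  one_et$X <- b$etongue$X[keep_et, ]; one_et$meta <- b$etongue$meta[keep_et, ]
  fused <- align_blocks(one_scan, one_et, b$enose)
  expect_equal(nrow(fused$X), 15)
  raw <- sweep(sweep(fused$X, 2, fused$scaler$sd, `*`), 2,
               -fused$scaler$mean)
  expect_equal(unname(raw),
               unname(cbind(one_scan$X, one_et$X, b$enose$X)),
               tolerance = 1e-9)
})

test_that("alignment rejects a sample missing from one block", {
  b <- make_three_blocks()
  short <- b$enose
  drop <- short$meta$class == "E" & short$meta$replicate == 2
  short$X <- short$X[!drop, ]; short$meta <- short$meta[!drop, ]
  expect_error(align_blocks(b$nir, b$etongue, short), "E/2")
})

test_that("whisker screening flags displaced predictions only", {
  g <- rep(c("a", "b"), each = 10)
  pred <- c(seq(0, 0.9, by = 0.1), 5 + seq(0, 0.9, by = 0.1))
  rep0 <- detect_prediction_outliers(pred, g)
  expect_length(rep0$flagged, 0)
  pred2 <- pred
  iqr <- diff(quantile(pred[1:10], c(0.25, 0.75)))
  pred2[3] <- median(pred[1:10]) + 10 * iqr
  rep1 <- detect_prediction_outliers(pred2, g)
  expect_equal(rep1$flagged, 3L)
  # identical predictions inside a group: zero IQR flags nothing extra
  rep2 <- detect_prediction_outliers(rep(c(1, 2), each = 5),
                                     rep(c("a", "b"), each = 5))
  expect_length(rep2$flagged, 0)
  # a value exactly on the whisker is retained
  vv <- c(1, 2, 3, 4, 5)
  b <- median(vv) + 1.5 * diff(quantile(vv, c(0.25, 0.75)))
  rep3 <- detect_prediction_outliers(c(vv[-5], b), rep("g", 5))
  expect_length(rep3$flagged, 0)
  expect_warning(detect_prediction_outliers(1:4, c("a", "a", "a", "b")),
                 "fewer than 3")
})

test_that("whisker screening is equivariant under affine rescaling", {
  set.seed(6)
  pred <- rnorm(40)
  g <- rep(letters[1:4], each = 10)
  base <- detect_prediction_outliers(pred, g)$flagged
  expect_equal(detect_prediction_outliers(3.7 * pred - 11, g)$flagged, base)
  expect_equal(detect_prediction_outliers(-2 * pred + 5, g)$flagged, base)
})

test_that("the Tukey whisker variant anchors on the quartiles", {
  v <- c(1, 2, 3, 4, 100)
  med <- detect_prediction_outliers(v, rep("g", 5), rule = "median")
  tuk <- detect_prediction_outliers(v, rep("g", 5), rule = "tukey")
  expect_equal(med$flagged, 5L)
  expect_equal(tuk$flagged, 5L)
  expect_gt(tuk$bounds$upper, med$bounds$upper)
})

test_that("two-round PLSR removes swapped-sample scans and improves", {
  # contamination: a few scans accidentally record another sample's
  # signal, so their predictions land in the wrong sample's cluster —
  # the case the per-sample boxplot of predicted values catches
  wins <- 0L
  for (s in 1:10) {
    set.seed(500 + s)
    classes <- rep(letters[1:5], each = 15)
    units <- rep(paste0("u", 1:15), each = 5)
    centre <- matrix(rnorm(5 * 8, sd = 3), 5)
    X <- centre[match(classes, letters[1:5]), ] +
      matrix(rnorm(75 * 8, sd = 0.3), 75)
    y <- c(0, 10, 20, 30, 40)[match(classes, letters[1:5])] +
      rnorm(75, sd = 0.3)
    bad <- c(4, 20, 60)                     # classes a, b, d
    swap <- c(3, 5, 1)                      # recorded signal's true class
    X[bad, ] <- centre[swap, ] + rnorm(length(swap) * 8, sd = 0.3)
    tr <- two_round_plsr(X, y, units, sample_of_row = classes,
                         max_latent = 5)
    if (all(bad %in% tr$outliers$flagged) &&
        tr$result$rmsecv < tr$round1$rmsecv) wins <- wins + 1L
    expect_equal(tr$result$n_obs, length(tr$kept))
  }
  expect_gte(wins, 9L)
})

test_that("two rounds coincide on clean data and flag few rows", {
  frac <- vapply(1:20, function(s) {
    toy <- toy_regression(n_units = 10, per_unit = 3, p = 5,
                          noise_sd = 0.5, seed = 700 + s)
    classes <- rep(letters[1:5], each = 6)
    tr <- two_round_plsr(toy$X, toy$y, toy$groups,
                         sample_of_row = classes, max_latent = 4)
    if (length(tr$outliers$flagged) == 0)
      expect_identical(tr$result, tr$round1)
    length(tr$outliers$flagged) / length(toy$y)
  }, numeric(1))
  expect_true(all(frac <= 0.25))
})
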