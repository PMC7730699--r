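#' Low-level fusion of NIR, e-tongue and e-nose blocks
#'
#' Concatenates the three pretreated instrument blocks into one
#' observations-by-features matrix on the NIR row basis. Rows are matched
#' by preparation unit (sample x replicate): e-tongue rows are paired
#' with NIR scans in acquisition order, re-using the unit average when a
#' unit has fewer e-tongue rows than NIR scans; the single e-nose row of
#' a unit is replicated across all of that unit's NIR rows. The fused
#' matrix is autoscaled after concatenation; the scaler is kept so any
#' block can be recovered on its original scale.
#'
#' @param nir a pretreated [spectral_block()].
#' @param etongue a drift-corrected [sensor_block()].
#' @param enose a sensor-selected [sensor_block()] with one row per
#'   preparation unit.
#' @return list of class `fused_block` with `X` (autoscaled), `meta`
#'   (NIR row metadata), `block_map` (data.frame column -> source block),
#'   `scaler`.
#' @export
align_blocks <- function(nir, etongue, enose) {
  stopifnot(inherits(nir, "spectral_block"), inherits(etongue, "sensor_block"),
            inherits(enose, "sensor_block"))
  unit_of <- function(meta) paste(meta$sample_id, meta$replicate, sep = "/")
  u_nir <- unit_of(nir$meta)
  u_et <- unit_of(etongue$meta)
  u_en <- unit_of(enose$meta)
  miss_et <- setdiff(unique(u_nir), unique(u_et))
  if (length(miss_et))
    stop("sample/replicate missing from e-tongue block: ",
         paste(miss_et, collapse = ", "))
  miss_en <- setdiff(unique(u_nir), unique(u_en))
  if (length(miss_en))
    stop("sample/replicate missing from e-nose block: ",
         paste(miss_en, collapse = ", "))
  if (max(table(u_en)) > 1)
    stop("e-nose block must have one row per preparation unit")

  n <- nrow(nir$X)
  Xet <- matrix(NA_real_, n, ncol(etongue$X))
  Xen <- matrix(NA_real_, n, ncol(enose$X))
  for (u in unique(u_nir)) {
    rn <- which(u_nir == u)
    re <- which(u_et == u)
    for (j in seq_along(rn)) {
      Xet[rn[j], ] <- if (j <= length(re)) etongue$X[re[j], ]
                      else colMeans(etongue$X[re, , drop = FALSE])
    }
    Xen[rn, ] <- matrix(enose$X[which(u_en == u), ], length(rn),
                        ncol(enose$X), byrow = TRUE)
  }
  X <- cbind(nir$X, Xet, Xen)
  colnames(X) <- c(paste0("nir_", nir$wavelengths), etongue$sensor_ids,
                   enose$sensor_ids)
  block_map <- data.frame(
    column = colnames(X),
    block = rep(c("nir", "etongue", "enose"),
                c(ncol(nir$X), ncol(Xet), ncol(Xen))))
  sc <- autoscale_fit_apply(X)
  structure(list(X = sc$train, meta = nir$meta, block_map = block_map,
                 scaler = sc$scaler),
            class = "fused_block")
}

#' Boxplot outlier screening of CV predictions
#'
#' Flags, within each sample group, predictions falling strictly outside
#' `median +/- 1.5 IQR` (the whisker rule applied about the median;
#' `rule = "tukey"` instead uses the classic quartile-anchored whiskers
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`). Values exactly on a whisker are
#' retained. Groups with fewer than 3 observations are skipped with a
#' warning.
#'
#' @param predictions numeric vector of (cross-validated) predictions.
#' @param groups sample-group label per prediction.
#' @param rule `"median"` (default) or `"tukey"`.
#' @return list of class `outlier_report` with `flagged` (row indices)
#'   and `bounds` (per-group whisker limits).
#' @export
detect_prediction_outliers <- function(predictions, groups,
                                       rule = c("median", "tukey")) {
  rule <- match.arg(rule)
  stopifnot(length(predictions) == length(groups))
  flagged <- integer(0)
  bounds <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3) {
      warning("group '", g, "' has fewer than 3 observations; skipped")
      next
    }
    v <- predictions[idx]
    iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE))
    lim <- if (rule == "median") {
      median(v) + c(-1.5, 1.5) * iqr
    } else {
      quantile(v, c(0.25, 0.75), names = FALSE) + c(-1.5, 1.5) * iqr
    }
    flagged <- c(flagged, idx[v < lim[1] | v > lim[2]])
    bounds[[length(bounds) + 1L]] <-
      data.frame(group = g, lower = lim[1], upper = lim[2])
  }
  structure(list(flagged = sort(flagged),
                 bounds = do.call(rbind, bounds)),
            class = "outlier_report")
}

#' Two-round PLSR with prediction-based outlier removal
#'
#' Round one fits a grouped cross-validated PLSR on all rows; its CV
#' predictions are screened per sample group with
#' [detect_prediction_outliers()]; round two refits on the retained rows.
#' Because screening happens per predicted attribute, different
#' attributes may retain different observation counts.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param groups CV grouping per row (preparation unit), passed to
#'   [crossval_plsr()].
#' @param sample_of_row sample-group label per row used for the outlier
#'   boxplots; defaults to `groups`.
#' @param max_latent,scale_x,preproc passed to [crossval_plsr()].
#' @param rule whisker rule for [detect_prediction_outliers()].
#' @return list of class `plsr_two_round` with `result` (round-2
#'   `plsr_cv`), `outliers` (the [detect_prediction_outliers()] report),
#'   `round1` (round-1 `plsr_cv`), `kept` (retained row indices).
#' @export
two_round_plsr <- function(X, y, groups, sample_of_row = groups,
                           max_latent = 10L, scale_x = FALSE,
                           preproc = NULL, rule = c("median", "tukey")) {
  rule <- match.arg(rule)
  round1 <- crossval_plsr(X, y, groups, max_latent, scale_x = scale_x,
                          preproc = preproc)
  rep1 <- detect_prediction_outliers(round1$cv_pred, sample_of_row, rule)
  keep <- setdiff(seq_len(nrow(as.matrix(X))), rep1$flagged)
  gone <- setdiff(unique(sample_of_row), unique(sample_of_row[keep]))
  if (length(gone))
    stop("outlier removal emptied sample group(s): ",
         paste(gone, collapse = ", "))
  round2 <- if (length(rep1$flagged)) {
    crossval_plsr(as.matrix(X)[keep, , drop = FALSE], y[keep],
                  groups[keep], max_latent, scale_x = scale_x,
                  preproc = preproc)
  } else round1
  structure(list(result = round2, outliers = rep1, round1 = round1,
                 kept = keep),
            class = "plsr_two_round")
}

#' @export
print.plsr_two_round <- function(x, ...) {
  cat("round 1: "); print(x$round1)
  cat(length(x$outliers$flagged), "outlier(s) removed\nround 2: ")
  print(x$result)
  invisible(x)
}
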