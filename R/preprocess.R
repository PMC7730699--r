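#' Savitzky-Golay smoothing of a spectral block
#'
#' Replaces each spectral point by the value (or `deriv`-th derivative) of
#' the local least-squares polynomial of order `polyorder` fitted over a
#' centred window of `window` points. At the spectrum ends the polynomial
#' is fitted on the truncated asymmetric window and evaluated at the
#' point itself, so no data are fabricated beyond the measured range.
#' Defaults (window 21, order 2, no derivative) are the standard noise
#' filter for transmission NIR spectra.
#'
#' @param block a [spectral_block()].
#' @param window odd integer filter length, `polyorder < window <= p`.
#' @param polyorder polynomial order.
#' @param deriv derivative order (0 = smoothed signal). Derivatives are in
#'   units of the (uniform) sampling step.
#' @return The smoothed [spectral_block()].
#' @export
savgol_smooth <- function(block, window = 21L, polyorder = 2L, deriv = 0L) {
  stopifnot(inherits(block, "spectral_block"))
  p <- ncol(block$X)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > p) stop("window exceeds number of wavelengths")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  W <- savgol_weights(p, window, polyorder, deriv)
  out <- block
  out$X <- block$X %*% t(W)
  dimnames(out$X) <- dimnames(block$X)
  out
}

# p x p weight matrix; row i holds the least-squares weights producing the
# deriv-th derivative of the local polynomial at point i. Interior rows
# share one stencil; edge rows use the truncated window.
savgol_weights <- function(p, window, polyorder, deriv) {
  h <- (window - 1L) %/% 2L
  W <- matrix(0, p, p)
  stencil <- function(idx, centre) {
    A <- outer(idx - centre, 0:polyorder, `^`)
    # row of (A'A)^-1 A' for the deriv-th coefficient, times deriv!
    e <- solve(crossprod(A), t(A))[deriv + 1L, ] * factorial(deriv)
    e
  }
  interior <- stencil(seq_len(window), h + 1L)
  for (i in seq_len(p)) {
    lo <- max(1L, i - h); hi <- min(p, i + h)
    if (hi - lo + 1L == window) {
      W[i, lo:hi] <- interior
    } else {
      W[i, lo:hi] <- stencil(lo:hi, i)
    }
  }
  W
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum (default: the column
#' mean of the block) and removes the fitted affine scatter: with slope
#' `a` and intercept `b` from `x ~ reference`, the corrected spectrum is
#' `(x - b) / a`. The reference used is returned so that held-out spectra
#' can be corrected with the training reference (no information leakage).
#'
#' @param block a [spectral_block()].
#' @param reference `"mean"` or a numeric spectrum of matching length.
#' @return list with elements `block` (corrected [spectral_block()]) and
#'   `reference` (the reference spectrum used).
#' @export
msc_correct <- function(block, reference = "mean") {
  stopifnot(inherits(block, "spectral_block"))
  ref <- if (identical(reference, "mean")) colMeans(block$X) else as.numeric(reference)
  if (length(ref) != ncol(block$X))
    stop("reference length does not match wavelength count")
  if (sd(ref) == 0) stop("constant reference: scatter slope undefined")
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  Xc <- sweep(block$X, 1, rowMeans(block$X))
  slope <- as.numeric(Xc %*% rc) / denom
  intercept <- rowMeans(block$X) - slope * mean(ref)
  out <- block
  out$X <- (block$X - intercept) / slope
  list(block = out, reference = ref)
}

#' Truncate a spectral block to a wavelength interval
#'
#' Retains wavelengths in the closed interval `[low_nm, high_nm]`; the
#' default 950-1650 nm drops the noisy edges of a 900-1700 nm instrument
#' range.
#'
#' @param block a [spectral_block()].
#' @param low_nm,high_nm interval bounds in nm.
#' @return The truncated [spectral_block()].
#' @export
truncate_range <- function(block, low_nm = 950, high_nm = 1650) {
  stopifnot(inherits(block, "spectral_block"), low_nm < high_nm ||
              low_nm == high_nm)
  keep <- block$wavelengths >= low_nm & block$wavelengths <= high_nm
  if (!any(keep)) stop("no wavelengths inside [", low_nm, ", ", high_nm, "]")
  out <- block
  out$X <- block$X[, keep, drop = FALSE]
  out$wavelengths <- block$wavelengths[keep]
  out
}

#' Column autoscaling fitted on training data
#'
#' Mean-centres and scales to unit standard deviation (n-1 denominator)
#' using statistics of the training matrix only; held-out rows are
#' transformed with the training means and SDs.
#'
#' @param train numeric training matrix.
#' @param apply_to optional matrix with the same columns to transform with
#'   the training statistics.
#' @return list with `train` (scaled training matrix), `applied` (scaled
#'   `apply_to`, or `NULL`), and `scaler` (list of `mean` and `sd`).
#' @export
autoscale_fit_apply <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  mu <- colMeans(train)
  sigma <- apply(train, 2, sd)
  bad <- which(sigma == 0)
  if (length(bad))
    stop("constant training column(s): ",
         paste(if (is.null(colnames(train))) bad else colnames(train)[bad],
               collapse = ", "))
  scale_with <- function(M)
    sweep(sweep(as.matrix(M), 2, mu), 2, sigma, `/`)
  list(train = scale_with(train),
       applied = if (is.null(apply_to)) NULL else scale_with(apply_to),
       scaler = list(mean = mu, sd = sigma))
}

#' Additive session-drift correction for e-tongue signals
#'
#' Potentiometric sensor arrays age between measurement sessions; when
#' every session measures the same sample set, the session-to-session
#' shift of a sensor is estimated as the difference between the session
#' mean over all samples and the sensor's grand mean, and subtracted from
#' every observation in that session ("additive correction relative to
#' all samples"). Per-sensor grand means and all within-session contrasts
#' are preserved exactly.
#'
#' @param block a [sensor_block()] whose `meta` has a `session` column.
#' @return The drift-corrected [sensor_block()].
#' @export
drift_correct_etongue <- function(block) {
  stopifnot(inherits(block, "sensor_block"))
  session <- block$meta$session
  if (is.null(session)) stop("metadata has no 'session' column")
  if (length(unique(session)) < 2) {
    warning("single session: no drift to correct, block returned unchanged")
    return(block)
  }
  out <- block
  grand <- colMeans(block$X)
  for (s in unique(session)) {
    rows <- which(session == s)
    shift <- colMeans(block$X[rows, , drop = FALSE]) - grand
    out$X[rows, ] <- sweep(block$X[rows, , drop = FALSE], 2, shift)
  }
  out
}

#' Per-sensor discrimination power (Fisher ratio)
#'
#' Between-class sum of squares divided by within-class sum of squares
#' for each sensor: high when groups are far apart and tight. A sensor
#' with zero variance scores 0; a perfect separator (zero within-class
#' variance, non-zero between) scores `Inf`.
#'
#' @param X numeric matrix, observations x sensors.
#' @param labels class label per row (>= 2 classes).
#' @return named numeric vector of scores, one per column.
#' @export
discrimination_power <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  grand <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
  for (g in levels(labels)) {
    rows <- which(labels == g)
    m <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + length(rows) * (m - grand)^2
    ssw <- ssw + colSums(sweep(X[rows, , drop = FALSE], 2, m)^2)
  }
  score <- ifelse(ssw == 0, ifelse(ssb == 0, 0, Inf), ssb / ssw)
  names(score) <- colnames(X)
  score
}

#' Select the most class-discriminating sensors
#'
#' Ranks sensors by [discrimination_power()] and keeps the top `k`
#' (default 20, the usual cut for ultra-fast GC e-nose arrays). Ties are
#' broken by sensor-id lexical order for determinism.
#'
#' @param block a [sensor_block()].
#' @param labels class label per row; defaults to `block$meta$class`.
#' @param k number of sensors to retain.
#' @return A [sensor_block()] with the selected sensors, carrying the full
#'   score vector as attribute `"discrimination_power"`.
#' @export
select_sensors_by_discrimination <- function(block, labels = NULL, k = 20L) {
  stopifnot(inherits(block, "sensor_block"))
  if (is.null(labels)) labels <- block$meta$class
  if (k > ncol(block$X)) stop("k exceeds sensor count")
  score <- discrimination_power(block$X, labels)
  ord <- order(-score, block$sensor_ids)
  keep <- sort(ord[seq_len(k)])
  out <- block
  out$X <- block$X[, keep, drop = FALSE]
  out$sensor_ids <- block$sensor_ids[keep]
  attr(out, "discrimination_power") <- score
  out
}
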