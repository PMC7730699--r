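# In-code fixtures shared across test files.

toy_spectral <- function(n = 6, wl = seq(900, 1700, by = 10), seed = 1,
                         f = function(w) 0.2 + 0.001 * w) {
  set.seed(seed)
  X <- t(vapply(seq_len(n), function(i)
    f(wl) + rnorm(length(wl), sd = 0.01), numeric(length(wl))))
  spectral_block(X, wl, data.frame(
    sample_id = paste0("s", rep(1:2, length.out = n)),
    class = rep(c("A", "B"), length.out = n),
    replicate = rep(1:3, length.out = n)))
}

toy_sensor <- function(X, classes = NULL, sessions = 1L,
                       ids = paste0("S", seq_len(ncol(X)))) {
  n <- nrow(X)
  if (is.null(classes)) classes <- rep(c("A", "B"), length.out = n)
  sensor_block(X, ids, data.frame(
    sample_id = classes, class = classes,
    replicate = rep(1L, n), session = rep(sessions, length.out = n)))
}

# deterministic multi-unit regression problem with grouped structure
toy_regression <- function(n_units = 15, per_unit = 5, p = 10, beta = NULL,
                           noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- c(2, -1, rep(0, p - 2))
  units <- rep(paste0("u", seq_len(n_units)), each = per_unit)
  X <- matrix(rnorm(n_units * per_unit * p), ncol = p)
  y <- drop(X %*% beta) + rnorm(length(units), sd = noise_sd)
  list(X = X, y = y, groups = units, beta = beta, noise_sd = noise_sd)
}
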