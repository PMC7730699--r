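#' Spectral block container
#'
#' An observations-by-wavelength absorbance matrix with per-row metadata,
#' the working unit for NIR data. Wavelengths must be strictly increasing
#' and match the matrix columns; missing values are not allowed.
#'
#' @param X numeric matrix, observations x wavelengths.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, length `ncol(X)`.
#' @param meta data.frame with one row per observation; expected columns
#'   `sample_id`, `class`, `replicate`, and optionally `scan`.
#' @return An object of class `spectral_block` with elements `X`,
#'   `wavelengths`, `meta`.
#' @seealso [sensor_block()]
#' @export
spectral_block <- function(X, wavelengths, meta) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(X))
    stop("wavelength count (", length(wavelengths),
         ") does not match matrix columns (", ncol(X), ")")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(X)) stop("spectral block contains missing values")
  meta <- check_block_meta(meta, nrow(X))
  structure(list(X = X, wavelengths = wavelengths, meta = meta),
            class = "spectral_block")
}

#' Sensor block container
#'
#' An observations-by-sensor signal matrix with per-row metadata, used for
#' electronic-nose and electronic-tongue data. Sensor identifiers must be
#' unique; missing values are not allowed.
#'
#' @param X numeric matrix, observations x sensors.
#' @param sensor_ids character vector of unique sensor names (e-nose IDs of
#'   the form `"<KI>-1A"`/`"<KI>-2A"`, e-tongue IDs such as `"ZZ"`, `"JE"`).
#' @param meta data.frame with one row per observation; expected columns
#'   `sample_id`, `class`, `replicate`, and optionally `session`.
#' @return An object of class `sensor_block` with elements `X`,
#'   `sensor_ids`, `meta`.
#' @export
sensor_block <- function(X, sensor_ids, meta) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  sensor_ids <- as.character(sensor_ids)
  if (length(sensor_ids) != ncol(X))
    stop("sensor id count does not match matrix columns")
  if (anyDuplicated(sensor_ids))
    stop("duplicate sensor ids: ",
         paste(unique(sensor_ids[duplicated(sensor_ids)]), collapse = ", "))
  if (anyNA(X)) stop("sensor block contains missing values")
  colnames(X) <- sensor_ids
  meta <- check_block_meta(meta, nrow(X))
  structure(list(X = X, sensor_ids = sensor_ids, meta = meta),
            class = "sensor_block")
}

check_block_meta <- function(meta, n) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    stop("metadata has ", nrow(meta), " rows for ", n, " observations")
  for (col in c("sample_id", "class", "replicate"))
    if (is.null(meta[[col]]))
      stop("metadata is missing required column '", col, "'")
  meta
}

#' @export
print.spectral_block <- function(x, ...) {
  cat("<spectral_block> ", nrow(x$X), " obs x ", ncol(x$X), " wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm), ",
      length(unique(x$meta$class)), " classes\n", sep = "")
  invisible(x)
}

#' @export
print.sensor_block <- function(x, ...) {
  cat("<sensor_block> ", nrow(x$X), " obs x ", ncol(x$X), " sensors, ",
      length(unique(x$meta$class)), " classes\n", sep = "")
  invisible(x)
}

#' @export
dim.spectral_block <- function(x) dim(x$X)

#' @export
dim.sensor_block <- function(x) dim(x$X)
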