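# Atomic write: write to a temp file in the target directory, then
# rename, so a failure never leaves a partial output behind.
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  ok <- TRUE
  invisible(path)
}

block_meta_cols <- c("sample_id", "class", "replicate", "session", "scan")

#' Read an instrument or observation block from CSV
#'
#' All blocks share one dialect: UTF-8 comma-separated values with a
#' header row of metadata columns (`sample_id`, `class`, `replicate`,
#' optionally `session`/`scan`) followed by feature columns — decimal
#' wavelength strings in nm for `kind = "nir"`, sensor IDs for
#' `"etongue"`/`"enose"`, score/coordinate columns for `"sensory"` and
#' `"colour"`. Feature cells must be numeric; NIR wavelength headers must
#' be strictly increasing.
#'
#' @param path CSV file path.
#' @param kind one of `"nir"`, `"etongue"`, `"enose"`, `"sensory"`,
#'   `"colour"`.
#' @return A [spectral_block()], [sensor_block()], or data.frame,
#'   depending on `kind`; row order is preserved.
#' @export
read_block <- function(path, kind = c("nir", "etongue", "enose", "sensory",
                                      "colour")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (kind == "sensory") return(validate_sensory_scores(df))
  if (kind == "colour") {
    need <- c("sample_id", "replicate", "L", "a", "b")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    return(df)
  }
  if (anyDuplicated(names(df)))
    stop("duplicate column header(s): ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  meta_cols <- intersect(block_meta_cols, names(df))
  if (!all(c("sample_id", "class", "replicate") %in% meta_cols))
    stop("missing metadata column(s): ",
         paste(setdiff(c("sample_id", "class", "replicate"), meta_cols),
               collapse = ", "))
  feat_cols <- setdiff(names(df), meta_cols)
  if (!length(feat_cols)) stop("no feature columns")
  X <- as.matrix(df[feat_cols])
  if (!is.numeric(X)) {
    bad <- which(!vapply(df[feat_cols], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(
      as.numeric(df[[feat_cols[bad]]]))))[1]
    stop("non-numeric value in column '", feat_cols[bad], "', row ",
         ifelse(is.na(badrow), 1L, badrow))
  }
  meta <- df[meta_cols]
  if (kind == "nir") {
    wl <- suppressWarnings(as.numeric(feat_cols))
    if (anyNA(wl)) stop("NIR feature headers must be wavelengths in nm")
    if (any(diff(wl) <= 0)) stop("wavelength headers must be strictly increasing")
    spectral_block(X, wl, meta)
  } else {
    sensor_block(X, feat_cols, meta)
  }
}

#' Write a block to CSV
#'
#' Inverse of [read_block()]: metadata columns first, then feature
#' columns (NIR wavelengths serialized with one decimal place). The
#' write is atomic.
#'
#' @param block a [spectral_block()], [sensor_block()], or data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  df <- if (inherits(block, "spectral_block")) {
    X <- block$X
    colnames(X) <- sprintf("%.1f", block$wavelengths)
    cbind(block$meta, as.data.frame(X, check.names = FALSE))
  } else if (inherits(block, "sensor_block")) {
    cbind(block$meta, as.data.frame(block$X, check.names = FALSE))
  } else {
    as.data.frame(block)
  }
  atomic_write(function(tmp)
    write.csv(df, tmp, row.names = FALSE, quote = TRUE), path)
}

#' Read a study configuration from YAML
#'
#' Any field of [study_config()] may be overridden; unknown fields are
#' rejected. Analysis settings (`sg_window`, `sg_polyorder`, `trunc_low`,
#' `trunc_high`, `n_sensors`, `lda_folds`, `lda_seed`, `max_latent`,
#' `alpha`, `outlier_rule`, `pretreat_scope`, `attributes`) are returned
#' alongside.
#'
#' @param path YAML file path.
#' @return list with `study` (a [study_config()]) and `analysis`.
#' @export
read_study_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  study_fields <- names(formals(study_config))
  analysis_defaults <- default_analysis_settings()
  unknown <- setdiff(names(raw), c(study_fields, names(analysis_defaults)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  study <- do.call(study_config, raw[intersect(names(raw), study_fields)])
  analysis <- utils::modifyList(analysis_defaults,
                                raw[intersect(names(raw),
                                              names(analysis_defaults))])
  list(study = study, analysis = analysis)
}

#' Default analysis settings
#'
#' The pipeline defaults: Savitzky-Golay window 21 / order 2, retained
#' range 950-1650 nm, 20 e-nose sensors, 3-fold LDA with seed 42, up to
#' 10 latent variables, alpha 0.05, median-anchored whisker rule, and
#' leakage-safe pretreatment scope (`"training"`).
#'
#' @return named list of settings.
#' @export
default_analysis_settings <- function() {
  list(sg_window = 21L, sg_polyorder = 2L,
       trunc_low = 950, trunc_high = 1650,
       n_sensors = 20L,
       lda_folds = 3L, lda_seed = 42L,
       max_latent = 10L,
       alpha = 0.05,
       outlier_rule = "median",
       pretreat_scope = "training",
       attributes = NULL)
}
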