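ref_path <- function(file) {
  p <- system.file("extdata", file, package = "pollenfuse")
  if (p == "") stop("reference file not found: ", file)
  p
}

#' Published colour reference of the five pollen samples
#'
#' Mean CIELAB coordinates (with SDs) per botanical sample, plus the
#' published chroma and hue-angle values, as reported for the study's
#' spectral colour measurement.
#'
#' @return data.frame with columns `sample`, `L`, `a`, `b`, `L_sd`,
#'   `a_sd`, `b_sd`, `chroma_printed`, `hue_printed`.
#' @export
pollen_colour_reference <- function() {
  read.csv(ref_path("colour_means_cielab.csv"), check.names = FALSE)
}

#' Published pairwise colour differences
#'
#' The reported ΔE*ab, ΔC*ab and Δh_ab values for all ten sample pairs.
#'
#' @return data.frame with columns `sample_1`, `sample_2`, `delta_E`,
#'   `delta_C`, `delta_h`.
#' @export
pollen_colour_differences <- function() {
  read.csv(ref_path("colour_differences_printed.csv"), check.names = FALSE)
}

#' Published sensory profile summary
#'
#' Per-attribute, per-sample means and SDs of the 18 quantitative
#' descriptive attributes (n = 28 scores behind each cell: 14 panellists
#' x 2 sessions).
#'
#' @return long data.frame with columns `attribute`, `sample`, `mean`,
#'   `sd`.
#' @export
sensory_reference_summary <- function() {
  read.csv(ref_path("sensory_qda_summary.csv"), check.names = FALSE)
}

#' Published PLSR model-quality tables
#'
#' Reported regression quality (R2 training / CV, RMSEC, RMSECV, RPD,
#' latent variables, observations) per predicted attribute for each
#' instrument block and for the fused data.
#'
#' @param block one of `"nir"`, `"enose"`, `"etongue"`, `"fused"`.
#' @return data.frame with columns `predicted_variable`, `r2_tr`,
#'   `rmsec`, `r2_cv`, `rmsecv`, `rpd`, `n_latent`, `n_obs`.
#' @export
plsr_reference_table <- function(block = c("nir", "enose", "etongue",
                                           "fused")) {
  block <- match.arg(block)
  read.csv(ref_path(paste0("plsr_quality_", block, ".csv")),
           check.names = FALSE)
}
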