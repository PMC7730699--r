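#' Configuration of the synthetic five-class pollen study
#'
#' Defines the study conditions the generator emulates: 5 botanical
#' classes x 3 preparation replicates, 5 consecutive NIR scans per
#' replicate (n = 75 spectra), 4 e-tongue measurement sessions (n = 60),
#' one e-nose observation per preparation unit (n = 15, the 5 mL / 60
#' degree headspace method), a 14-panellist x 2-session sensory panel,
#' and 10 colour readings per class. Class mean structures for colour and
#' sensory attributes are taken from the published summary tables shipped
#' with the package; instrument-block class separations, noise scales and
#' drift magnitudes are generator defaults chosen once so that the
#' study's qualitative outcomes (NIR and e-nose classification at
#' ceiling, e-tongue confusable only between the two Carduus-containing
#' polyfloral samples) emerge from realistic signal-to-noise ratios.
#'
#' @param seed master seed; all sub-block seeds derive from it.
#' @param replicates preparation replicates per class.
#' @param nir_scans consecutive NIR scans per replicate.
#' @param etongue_sessions e-tongue sessions (each measures every unit).
#' @param panellists,sensory_sessions sensory panel design.
#' @param colour_obs_per_class colour readings per class.
#' @param nir_noise_sd absorbance noise SD per wavelength.
#' @param nir_gain_range,nir_offset_range multiplicative gain and
#'   additive offset ranges of the per-scan scatter effect.
#' @param etongue_noise_sd,etongue_drift_sd measurement noise and
#'   additive per-session drift SD (signal units).
#' @param enose_n_sensors,enose_informative,enose_noise_sd,enose_class_sep
#'   e-nose sensor pool size, number of class-informative sensors (with
#'   graded discrimination power), noise SD and top separation scale.
#' @param latent_effect slope of each block latent factor on the
#'   attributes, in units of the attribute's between-class SD.
#' @param attr_noise residual attribute noise, same units.
#' @param assessor_sd SD of additive panellist effects (score points).
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 20L,
                         replicates = 3L,
                         nir_scans = 5L,
                         etongue_sessions = 4L,
                         panellists = 14L,
                         sensory_sessions = 2L,
                         colour_obs_per_class = 10L,
                         nir_noise_sd = 0.002,
                         nir_gain_range = c(0.9, 1.1),
                         nir_offset_range = c(-0.05, 0.05),
                         etongue_noise_sd = 3,
                         etongue_drift_sd = 10,
                         enose_n_sensors = 59L,
                         enose_informative = 20L,
                         enose_noise_sd = 1,
                         enose_class_sep = 12,
                         latent_effect = 0.25,
                         attr_noise = 0.05,
                         assessor_sd = 2) {
  cfg <- as.list(environment())
  cfg$classes <- c("lakeshore bulrush", "sunflower", "red clover",
                   "rapeseed", "spiny plumeless thistle")
  stopifnot(replicates > 0, nir_scans > 0, etongue_sessions > 0,
            panellists > 0, sensory_sessions > 0,
            enose_informative <= enose_n_sensors)
  structure(cfg, class = "study_config")
}

# deterministic sub-seeds below 2^31, one stream per block
sub_seed <- function(seed, k) (as.numeric(seed) + k * 7919) %% 2147483647

# preparation-unit table: 5 classes x `replicates`
unit_table <- function(config) {
  data.frame(
    unit = paste(rep(config$classes, each = config$replicates),
                 rep(seq_len(config$replicates), length(config$classes)),
                 sep = "/"),
    class = rep(config$classes, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(config$classes)))
}

# unit-level latent factors: z1 expressed in NIR, z2 in e-tongue, z3 in
# e-nose; attributes load on all three, which is what makes fusion
# informative beyond the class means
unit_latents <- function(config) {
  u <- unit_table(config)
  with_seed(sub_seed(config$seed, 1L), {
    z <- matrix(rnorm(nrow(u) * 3), nrow(u), 3,
                dimnames = list(u$unit, c("z1", "z2", "z3")))
  })
  z
}

nir_band_centres <- c(1163, 1364, 1415, 1450, 1495)
nir_band_widths <- c(35, 45, 30, 40, 35)

# class-dependent band amplitudes; variation concentrated at 1364 and
# 1450 nm (free vs H-bonded water) so those bands drive PC1
nir_class_amps <- function(classes) {
  amps <- cbind(
    `1163` = c(0.000, 0.005, 0.010, 0.015, 0.020),
    `1364` = c(0.00, 0.16, 0.04, 0.20, 0.08),
    `1415` = c(0.020, 0.000, 0.010, 0.030, 0.015),
    `1450` = c(0.12, 0.00, 0.20, 0.04, 0.16),
    `1495` = c(0.010, 0.020, 0.000, 0.015, 0.030))
  rownames(amps) <- classes
  amps
}

#' Generate synthetic NIR transmission spectra
#'
#' 900-1700 nm at a 3 nm step. Each spectrum is a water-dominated base
#' (broad O-H bands) plus class-dependent Gaussian band amplitudes at
#' 1163 / 1364 / 1415 / 1450 / 1495 nm — the 1364 and 1450 nm bands carry
#' the largest between-class variation — modulated by the unit latent
#' factor `z1`, then distorted by a per-scan multiplicative gain
#' U(0.9, 1.1) and additive offset (removable by MSC) and white noise.
#'
#' @param config a [study_config()].
#' @param latents optional unit-by-3 latent matrix (shared with the other
#'   blocks by [generate_study()]); drawn internally when `NULL`.
#' @return A [spectral_block()] with
#'   `5 * replicates * nir_scans` rows.
#' @export
generate_nir_spectra <- function(config = study_config(), latents = NULL) {
  u <- unit_table(config)
  if (is.null(latents)) latents <- unit_latents(config)
  wl <- seq(900, 1700, by = 3)
  gauss <- function(c0, w) exp(-0.5 * ((wl - c0) / w)^2)
  base <- 0.10 + 1.10 * gauss(1450, 65) + 0.35 * gauss(1364, 45) +
    0.12 * gauss(1163, 35)
  bands <- vapply(seq_along(nir_band_centres),
                  function(b) gauss(nir_band_centres[b], nir_band_widths[b]),
                  numeric(length(wl)))
  amps <- nir_class_amps(config$classes)

  n <- nrow(u) * config$nir_scans
  X <- matrix(0, n, length(wl))
  meta <- data.frame(sample_id = rep(u$class, each = config$nir_scans),
                     class = rep(u$class, each = config$nir_scans),
                     replicate = rep(u$replicate, each = config$nir_scans),
                     scan = rep(seq_len(config$nir_scans), nrow(u)))
  with_seed(sub_seed(config$seed, 2L), {
    row <- 0L
    for (i in seq_len(nrow(u))) {
      a <- amps[u$class[i], ]
      a["1364"] <- a["1364"] + 0.010 * latents[i, "z1"]
      a["1450"] <- a["1450"] + 0.008 * latents[i, "z1"]
      clean <- base + drop(bands %*% a)
      for (s in seq_len(config$nir_scans)) {
        row <- row + 1L
        gain <- runif(1, config$nir_gain_range[1], config$nir_gain_range[2])
        offset <- runif(1, config$nir_offset_range[1],
                        config$nir_offset_range[2])
        X[row, ] <- gain * clean + offset +
          rnorm(length(wl), sd = config$nir_noise_sd)
      }
    }
  })
  spectral_block(X, wl, meta)
}

# e-tongue sensor set (ISFET array) and class mean patterns; the two
# Carduus-containing samples (lakeshore bulrush, spiny plumeless
# thistle) are placed close together, the unifloral samples far apart
etongue_sensor_ids <- c("ZZ", "JE", "JB", "HA", "CA", "BB", "DA")

etongue_class_means <- function(classes) {
  m <- rbind(
    c(30, 0, 15, -20, 10, 5, -10),                    # lakeshore bulrush
    c(-25, 30, -10, 15, -20, 25, 0),                  # sunflower
    c(10, -25, 30, 25, 0, -15, 20),                   # red clover
    c(-15, -10, -25, -30, 25, 10, 15),                # rapeseed
    c(30, 0, 15, -20, 10, 5, -10) +
      c(8, -6, 5, 0, -5, 4, 0))                       # spiny plumeless thistle
  m <- m + 500
  dimnames(m) <- list(classes, etongue_sensor_ids)
  m
}

#' Generate synthetic e-tongue signals with session drift
#'
#' Seven ISFET sensors, every preparation unit measured once in each of
#' `etongue_sessions` sessions. A per-session additive drift vector
#' (shared identically by all observations of the session, emulating
#' sensor ageing) is superimposed on class means, a unit latent factor
#' `z2`, and white noise; the injected drift is stored in the attribute
#' `"drift"` so correction can be verified exactly.
#'
#' @inheritParams generate_nir_spectra
#' @return A [sensor_block()] with session metadata.
#' @export
generate_etongue_with_drift <- function(config = study_config(),
                                        latents = NULL) {
  u <- unit_table(config)
  if (is.null(latents)) latents <- unit_latents(config)
  m <- etongue_class_means(config$classes)
  # z2 loading chosen orthogonal to the polyfloral pair's mean difference
  # so unit-to-unit taste variation does not blur the confusable pair
  loading <- c(3, 4, 0, 5, 2, 2.5, 4)
  n_sessions <- config$etongue_sessions
  n <- nrow(u) * n_sessions
  X <- matrix(0, n, length(etongue_sensor_ids))
  meta <- data.frame(sample_id = rep(u$class, times = n_sessions),
                     class = rep(u$class, times = n_sessions),
                     replicate = rep(u$replicate, times = n_sessions),
                     session = rep(seq_len(n_sessions), each = nrow(u)))
  with_seed(sub_seed(config$seed, 3L), {
    # standard draws scaled afterwards: the RNG stream is identical for
    # any drift magnitude, so a zero-drift twin study is exactly the same
    # data minus the drift
    drift <- config$etongue_drift_sd *
      matrix(rnorm(n_sessions * length(etongue_sensor_ids)),
             n_sessions, length(etongue_sensor_ids))
    for (r in seq_len(n)) {
      i <- (r - 1L) %% nrow(u) + 1L
      s <- meta$session[r]
      X[r, ] <- m[u$class[i], ] + loading * latents[i, "z2"] + drift[s, ] +
        rnorm(length(etongue_sensor_ids), sd = config$etongue_noise_sd)
    }
  })
  out <- sensor_block(X, etongue_sensor_ids, meta)
  attr(out, "drift") <- drift
  out
}

# e-nose sensor ids: Kovats-index labels on the two GC columns; the first
# informative ids match sensors reported as discriminating in this
# application domain, the rest of the pool is synthetic
enose_sensor_ids <- function(n) {
  named <- c("516.65-2A", "686.62-1A", "793.68-2A", "592.01-2A",
             "998.58-1A", "1046.00-1A", "444.97-1A")
  ki <- sprintf("%.2f-%s", seq(310, by = 23.7, length.out = n),
                rep(c("1A", "2A"), length.out = n))
  ids <- c(named, setdiff(ki, named))[seq_len(n)]
  ids
}

#' Generate synthetic e-nose signals
#'
#' One observation per preparation unit (headspace method with the best
#' discrimination). From a pool of `enose_n_sensors` sensors,
#' `enose_informative` carry class-dependent mean patterns with linearly
#' graded separation (hence graded Fisher discrimination power); the
#' remainder is pure noise. The first ten informative sensors also load
#' on the unit latent factor `z3`.
#'
#' @inheritParams generate_nir_spectra
#' @return A [sensor_block()] with 5 x `replicates` rows.
#' @export
generate_enose <- function(config = study_config(), latents = NULL) {
  u <- unit_table(config)
  if (is.null(latents)) latents <- unit_latents(config)
  p <- config$enose_n_sensors
  k_inf <- config$enose_informative
  ids <- enose_sensor_ids(p)
  base_pattern <- c(-1, -0.5, 0, 0.5, 1)
  grade <- seq(1, 0.3, length.out = k_inf)
  X <- matrix(0, nrow(u), p)
  with_seed(sub_seed(config$seed, 4L), {
    X[] <- rnorm(length(X), sd = config$enose_noise_sd)
    for (j in seq_len(k_inf)) {
      # rotate the class pattern so sensors discriminate different pairs
      patt <- base_pattern[((seq_len(5) + j) %% 5) + 1L]
      cls_mean <- config$enose_class_sep * grade[j] * patt
      X[, j] <- X[, j] + cls_mean[match(u$class, config$classes)]
      if (j <= 10L) X[, j] <- X[, j] + 2.0 * latents[, "z3"]
    }
  })
  meta <- data.frame(sample_id = u$class, class = u$class,
                     replicate = u$replicate, session = 1L)
  out <- sensor_block(X, ids, meta)
  attr(out, "informative") <- ids[seq_len(k_inf)]
  out
}

#' Generate synthetic colour observations
#'
#' Gaussian (L*, a*, b*) readings around the per-class means and SDs of
#' the packaged colour reference table, `colour_obs_per_class` per class.
#'
#' @inheritParams generate_nir_spectra
#' @return data.frame with columns `sample_id`, `class`, `replicate`,
#'   `L`, `a`, `b`.
#' @export
generate_colour_observations <- function(config = study_config()) {
  ref <- pollen_colour_reference()
  n <- config$colour_obs_per_class
  with_seed(sub_seed(config$seed, 5L), {
    out <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
      data.frame(sample_id = ref$sample[i], class = ref$sample[i],
                 replicate = seq_len(n),
                 L = rnorm(n, ref$L[i], ref$L_sd[i]),
                 a = rnorm(n, ref$a[i], ref$a_sd[i]),
                 b = rnorm(n, ref$b[i], ref$b_sd[i]))
    }))
  })
  rownames(out) <- NULL
  out
}

#' Generate a synthetic sensory panel table
#'
#' Long quantitative-descriptive-profile table: per attribute, scores are
#' the class means of the packaged sensory summary plus additive
#' panellist effects and residual noise (0.6 of the published
#' within-sample SD, floored at 0.3), truncated to the 0-100 scale.
#' Panellist effects are additive only — no scaling heterogeneity.
#'
#' @inheritParams generate_nir_spectra
#' @return long data.frame with columns `panellist`, `session`, `sample`,
#'   `attribute`, `score`.
#' @export
generate_sensory_scores <- function(config = study_config()) {
  ref <- sensory_reference_summary()
  atts <- unique(ref$attribute)
  design <- expand.grid(panellist = seq_len(config$panellists),
                        session = seq_len(config$sensory_sessions),
                        sample = config$classes,
                        stringsAsFactors = FALSE)
  with_seed(sub_seed(config$seed, 6L), {
    out <- do.call(rbind, lapply(atts, function(att) {
      sub <- ref[ref$attribute == att, ]
      mu <- setNames(sub$mean, sub$sample)
      res_sd <- setNames(pmax(0.6 * sub$sd, 0.3), sub$sample)
      assess <- rnorm(config$panellists, sd = config$assessor_sd)
      score <- mu[design$sample] + assess[design$panellist] +
        rnorm(nrow(design), sd = res_sd[design$sample])
      data.frame(design, attribute = att,
                 score = pmin(100, pmax(0, score)))
    }))
  })
  rownames(out) <- NULL
  out
}

# per-unit attribute values for regression: class mean + latent loadings
# (in units of the attribute's between-class SD) + noise. Colour
# attributes L*, a*, b* plus each sample's chroma/hue offset from the
# study mean colour are appended to the 18 sensory attributes.
generate_unit_attributes <- function(config, latents) {
  u <- unit_table(config)
  sens <- sensory_reference_summary()
  col <- pollen_colour_reference()
  ch <- derive_chroma_hue(col$L, col$a, col$b)
  class_means <- lapply(split(sens, sens$attribute), function(s)
    setNames(s$mean, s$sample))
  class_means$L_star <- setNames(col$L, col$sample)
  class_means$a_star <- setNames(col$a, col$sample)
  class_means$b_star <- setNames(col$b, col$sample)
  class_means$delta_C <- setNames(ch$chroma - mean(ch$chroma), col$sample)
  class_means$delta_h <- setNames(ch$hue_deg - mean(ch$hue_deg), col$sample)

  vals <- list()
  with_seed(sub_seed(config$seed, 7L), {
    for (att in names(class_means)) {
      mu <- class_means[[att]][u$class]
      S <- sd(class_means[[att]])
      vals[[att]] <- as.numeric(mu) +
        config$latent_effect * S * rowSums(latents) +
        rnorm(nrow(u), sd = config$attr_noise * S)
    }
  })
  cbind(u, as.data.frame(vals, check.names = FALSE))
}

#' Generate the full synthetic study
#'
#' Draws the shared unit latent factors once, then every block from its
#' own deterministic sub-seed: colour observations, the NIR block
#' (n = 75 for the default design), the e-tongue block with session
#' drift, the e-nose block, the sensory panel table, and per-unit
#' attribute values whose dependence on all three block latents makes
#' fusion informative. The ground truth (latents, injected drift,
#' informative sensors, attribute coefficient scale) is returned for
#' recovery tests.
#'
#' @param config a [study_config()].
#' @return list of class `pollen_study` with elements `colour`, `nir`,
#'   `etongue`, `enose`, `sensory`, `attributes` (per-unit values),
#'   `ground_truth`, `config`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  z <- unit_latents(config)
  nir <- generate_nir_spectra(config, z)
  etongue <- generate_etongue_with_drift(config, z)
  enose <- generate_enose(config, z)
  attributes <- generate_unit_attributes(config, z)
  structure(list(
    colour = generate_colour_observations(config),
    nir = nir,
    etongue = etongue,
    enose = enose,
    sensory = generate_sensory_scores(config),
    attributes = attributes,
    ground_truth = list(latents = z,
                        drift = attr(etongue, "drift"),
                        informative_sensors = attr(enose, "informative"),
                        latent_effect = config$latent_effect),
    config = config
  ), class = "pollen_study")
}

#' @export
print.pollen_study <- function(x, ...) {
  cat("<pollen_study> seed", x$config$seed, "|",
      nrow(x$nir$X), "NIR spectra,", nrow(x$etongue$X), "e-tongue obs,",
      nrow(x$enose$X), "e-nose obs,", nrow(x$sensory), "sensory scores\n")
  invisible(x)
}
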