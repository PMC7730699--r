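row_units <- function(meta) paste(meta$sample_id, meta$replicate, sep = "/")

#' Pretreat a NIR block
#'
#' Savitzky-Golay smoothing, multiplicative scatter correction against
#' the block mean, and truncation to the informative wavelength range,
#' in that order.
#'
#' @param block a [spectral_block()].
#' @param sg_window,sg_polyorder Savitzky-Golay filter settings.
#' @param trunc_low,trunc_high retained wavelength interval in nm.
#' @return the pretreated [spectral_block()].
#' @export
pretreat_nir <- function(block, sg_window = 21L, sg_polyorder = 2L,
                         trunc_low = 950, trunc_high = 1650) {
  sm <- savgol_smooth(block, sg_window, sg_polyorder)
  truncate_range(msc_correct(sm)$block, trunc_low, trunc_high)
}

# leakage-safe NIR pretreatment hook for grouped CV: the MSC reference is
# the training-fold mean; truncation is a fixed column subset
nir_cv_preproc <- function(wavelengths, trunc_low, trunc_high) {
  keep <- wavelengths >= trunc_low & wavelengths <= trunc_high
  msc_rows <- function(M, ref) {
    rc <- ref - mean(ref)
    slope <- as.numeric(sweep(M, 1, rowMeans(M)) %*% rc) / sum(rc^2)
    intercept <- rowMeans(M) - slope * mean(ref)
    (M - intercept) / slope
  }
  function(train_X, test_X) {
    ref <- colMeans(train_X)
    list(train = msc_rows(train_X, ref)[, keep, drop = FALSE],
         test = msc_rows(test_X, ref)[, keep, drop = FALSE])
  }
}

#' Run the full synthetic fusion study
#'
#' Orchestrates the complete analysis on a generated study: block
#' pretreatment (NIR smoothing/scatter correction/truncation, e-tongue
#' drift correction, e-nose sensor selection), per-block PCA and
#' cross-validated LDA classification by botanical origin, per-block
#' two-round PLSR for every sensory and colour attribute, and the same
#' PLSR on the fused block. Deterministic given `config$seed` and the
#' analysis settings.
#'
#' @param config a [study_config()].
#' @param analysis analysis settings, see [default_analysis_settings()];
#'   `pretreat_scope = "training"` refits the NIR MSC reference and all
#'   scalers on training folds only inside cross-validation, `"full"`
#'   pretreats each block once.
#' @param blocks character subset of
#'   `c("nir", "etongue", "enose", "fused")` to run PLSR on.
#' @return list of class `study_report` with `lda`, `pca`, `plsr` (one
#'   data.frame per block), `study`, `config`, `analysis`.
#' @export
run_full_study <- function(config = study_config(),
                           analysis = default_analysis_settings(),
                           blocks = c("nir", "etongue", "enose", "fused")) {
  analysis <- utils::modifyList(default_analysis_settings(), analysis)
  study <- generate_study(config)

  nir_sg <- savgol_smooth(study$nir, analysis$sg_window,
                          analysis$sg_polyorder)
  nir_p <- truncate_range(msc_correct(nir_sg)$block,
                          analysis$trunc_low, analysis$trunc_high)
  et_c <- drift_correct_etongue(study$etongue)
  en_s <- select_sensors_by_discrimination(study$enose,
                                           k = analysis$n_sensors)

  scaled <- list(nir = autoscale_fit_apply(nir_p$X)$train,
                 etongue = autoscale_fit_apply(et_c$X)$train,
                 enose = autoscale_fit_apply(en_s$X)$train)
  metas <- list(nir = nir_p$meta, etongue = et_c$meta, enose = en_s$meta)

  pca <- lapply(scaled, function(X)
    fit_pca(X, n_components = min(5L, nrow(X) - 1L, ncol(X))))
  lda <- lapply(names(scaled), function(b)
    crossval_lda(scaled[[b]], metas[[b]]$class,
                 n_folds = analysis$lda_folds, seed = analysis$lda_seed))
  names(lda) <- names(scaled)

  fused <- align_blocks(nir_p, et_c, en_s)

  atts <- analysis$attributes
  if (is.null(atts))
    atts <- setdiff(names(study$attributes), c("unit", "class", "replicate"))
  att_val <- function(att, units)
    study$attributes[[att]][match(units, study$attributes$unit)]

  leakage_safe <- identical(analysis$pretreat_scope, "training")
  plsr_inputs <- list(
    nir = if (leakage_safe) {
      list(X = nir_sg$X, meta = nir_sg$meta, scale_x = TRUE,
           preproc = nir_cv_preproc(nir_sg$wavelengths,
                                    analysis$trunc_low,
                                    analysis$trunc_high))
    } else {
      list(X = nir_p$X, meta = nir_p$meta, scale_x = TRUE, preproc = NULL)
    },
    etongue = list(X = et_c$X, meta = et_c$meta, scale_x = TRUE,
                   preproc = NULL),
    enose = list(X = en_s$X, meta = en_s$meta, scale_x = TRUE,
                 preproc = NULL),
    fused = list(X = fused$X, meta = fused$meta, scale_x = FALSE,
                 preproc = NULL))

  plsr <- lapply(blocks, function(b) {
    inp <- plsr_inputs[[b]]
    units <- row_units(inp$meta)
    rows <- lapply(atts, function(att) {
      y <- att_val(att, units)
      tr <- two_round_plsr(inp$X, y, groups = units,
                           sample_of_row = inp$meta$class,
                           max_latent = analysis$max_latent,
                           scale_x = inp$scale_x, preproc = inp$preproc,
                           rule = analysis$outlier_rule)
      r <- tr$result
      data.frame(predicted_variable = att,
                 r2_tr = r$r2_tr, rmsec = r$rmsec,
                 r2_cv = r$r2_cv, rmsecv = r$rmsecv, rpd = r$rpd,
                 n_latent = r$n_latent, n_obs = r$n_obs,
                 n_outliers = length(tr$outliers$flagged))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
  names(plsr) <- blocks

  structure(list(lda = lda, pca = pca, plsr = plsr, fused = fused,
                 study = study, config = config, analysis = analysis),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$config$seed, "\nLDA prediction ability (%):\n")
  for (b in names(x$lda))
    cat(sprintf("  %-8s recognition %6.2f  prediction %6.2f\n", b,
                x$lda[[b]]$recognition_pct, x$lda[[b]]$prediction_pct))
  for (b in names(x$plsr))
    cat(sprintf("PLSR %-8s median R2cv %.3f over %d attributes\n", b,
                median(x$plsr[[b]]$r2_cv), nrow(x$plsr[[b]])))
  invisible(x)
}

#' Write a study report to disk
#'
#' One CSV per PLSR block table, an LDA/PCA summary CSV, and a JSON
#' bundle of the headline numbers. All writes are atomic and
#' deterministic for a given report.
#'
#' @param report a [run_full_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 10,
                                                   format = "g"))
    df
  }
  for (b in names(report$plsr))
    write_block(fmt(report$plsr[[b]]),
                file.path(dir, paste0("plsr_", b, ".csv")))
  lda_df <- do.call(rbind, lapply(names(report$lda), function(b)
    data.frame(block = b,
               recognition_pct = report$lda[[b]]$recognition_pct,
               prediction_pct = report$lda[[b]]$prediction_pct)))
  write_block(fmt(lda_df), file.path(dir, "lda_summary.csv"))
  pca_df <- do.call(rbind, lapply(names(report$pca), function(b)
    data.frame(block = b,
               pc1_variance_pct = report$pca[[b]]$explained_variance_pct[1],
               pc2_variance_pct = report$pca[[b]]$explained_variance_pct[2])))
  write_block(fmt(pca_df), file.path(dir, "pca_summary.csv"))
  bundle <- list(seed = report$config$seed,
                 lda = lapply(report$lda, function(l)
                   list(recognition_pct = l$recognition_pct,
                        prediction_pct = l$prediction_pct)),
                 plsr_median_r2_cv = lapply(report$plsr, function(t)
                   median(t$r2_cv)))
  atomic_write(function(tmp)
    jsonlite::write_json(bundle, tmp, auto_unbox = TRUE, digits = 10),
    file.path(dir, "report.json"))
  invisible(dir)
}
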