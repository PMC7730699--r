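# Run code with a local RNG state so package functions taking a `seed`
# argument do not clobber the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Principal component analysis
#'
#' Thin wrapper around [stats::prcomp()] returning scores, loadings and
#' the percentage of variance explained per component, the quantities
#' used for pattern inspection and for compressing wide blocks before
#' LDA.
#'
#' @param X numeric feature matrix (centred internally).
#' @param n_components number of components to keep; truncated with a
#'   warning if it exceeds `min(nrow - 1, ncol)`.
#' @return list of class `pf_pca` with `scores`, `loadings`,
#'   `explained_variance_pct`, `center`, `sdev`.
#' @export
fit_pca <- function(X, n_components = NULL) {
  X <- as.matrix(X)
  k_max <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max) {
    warning("n_components truncated to ", k_max)
    n_components <- k_max
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  structure(list(
    scores = pc$x[, keep, drop = FALSE],
    loadings = pc$rotation[, keep, drop = FALSE],
    explained_variance_pct = 100 * pc$sdev^2 / sum(pc$sdev^2),
    center = pc$center,
    sdev = pc$sdev
  ), class = "pf_pca")
}

# Stratified fold assignment: classes are shuffled independently and dealt
# round-robin so every fold sees every class.
stratified_folds <- function(y, n_folds, seed = 42L) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (g in levels(y)) {
      idx <- sample(which(y == g))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Pooled-covariance linear classifier used when MASS::lda rejects a
# singular pooled covariance; stabilized with a ridge of 1e-8 x mean
# diagonal.
ridge_lda_predict <- function(Xtr, ytr, Xte) {
  ytr <- as.factor(ytr)
  p <- ncol(Xtr)
  S <- matrix(0, p, p)
  mus <- lapply(levels(ytr), function(g) {
    rows <- which(ytr == g)
    m <- colMeans(Xtr[rows, , drop = FALSE])
    S <<- S + crossprod(sweep(Xtr[rows, , drop = FALSE], 2, m))
    m
  })
  S <- S / (nrow(Xtr) - nlevels(ytr))
  S <- S + diag(1e-8 * mean(diag(S)), p)
  Sinv <- solve(S)
  disc <- vapply(mus, function(m) {
    as.numeric(Xte %*% Sinv %*% m - 0.5 * drop(m %*% Sinv %*% m))
  }, numeric(nrow(Xte)))
  if (nrow(Xte) == 1L) disc <- matrix(disc, nrow = 1L)
  factor(levels(ytr)[max.col(disc)], levels = levels(ytr))
}

lda_train_predict <- function(Xtr, ytr, Xte) {
  fit <- tryCatch(MASS::lda(Xtr, grouping = ytr),
                  error = function(e) NULL)
  if (is.null(fit)) return(ridge_lda_predict(Xtr, ytr, Xte))
  predict(fit, Xte)$class
}

# Fit-on-train PCA compression retaining `var_explained` of the variance,
# capped at n_train - n_classes components.
compress_scores <- function(Xtr, Xte, n_classes, var_explained = 0.99) {
  pc <- prcomp(Xtr, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  m <- which(cum >= var_explained)[1]
  m <- min(m, nrow(Xtr) - n_classes, sum(pc$sdev > 1e-10))
  m <- max(m, 1L)
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  list(train = pc$x[, seq_len(m), drop = FALSE],
       test = sweep(Xte, 2, pc$center) %*% rot)
}

#' Cross-validated linear discriminant analysis
#'
#' Pooled-covariance LDA for botanical-origin classification with
#' stratified k-fold cross-validation. When the block is wider than it is
#' tall (`compress = "auto"`, e.g. a pretreated NIR block), each training
#' set is first compressed to PCA scores retaining 99% of its variance,
#' capped at `n_train - n_classes` components, and held-out rows are
#' projected with the training loadings — no information leaks across
#' folds. Recognition ability is the macro-averaged per-class accuracy of
#' the model refit on all rows; prediction ability is the macro-averaged
#' cross-validated accuracy.
#'
#' @param X numeric feature matrix.
#' @param y class labels, every class with at least `n_folds` members.
#' @param n_folds number of folds (default 3).
#' @param seed seed for the stratified fold assignment (default 42,
#'   reported in the result).
#' @param compress `"auto"` (compress when `ncol >= nrow` of the training
#'   fold), `"always"`, or `"never"`.
#' @param var_explained PCA variance retained under compression.
#' @return list of class `lda_cv` with `confusion_train`, `confusion_cv`,
#'   `recognition_pct`, `prediction_pct`, `root_scores`,
#'   `root_variance_pct`, `folds`, `seed`.
#' @export
crossval_lda <- function(X, y, n_folds = 3L, seed = 42L,
                         compress = c("auto", "always", "never"),
                         var_explained = 0.99) {
  X <- as.matrix(X)
  y <- as.factor(y)
  compress <- match.arg(compress)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < n_folds))
    stop("every class needs at least n_folds = ", n_folds, " members")
  fold <- stratified_folds(y, n_folds, seed)
  use_compress <- function(ntr) switch(compress,
    auto = ncol(X) >= ntr, always = TRUE, never = FALSE)

  cv_pred <- factor(rep(NA, length(y)), levels = levels(y))
  for (k in seq_len(n_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (use_compress(length(tr))) {
      cs <- compress_scores(Xtr, Xte, nlevels(y), var_explained)
      Xtr <- cs$train; Xte <- cs$test
    }
    cv_pred[te] <- lda_train_predict(Xtr, y[tr], Xte)
  }

  Xall <- X
  if (use_compress(nrow(X)))
    Xall <- compress_scores(X, X, nlevels(y), var_explained)$train
  full <- tryCatch(MASS::lda(Xall, grouping = y), error = function(e) NULL)
  if (!is.null(full)) {
    pr <- predict(full, Xall)
    train_pred <- pr$class
    roots <- pr$x
    root_var <- 100 * full$svd^2 / sum(full$svd^2)
  } else {
    train_pred <- ridge_lda_predict(Xall, y, Xall)
    roots <- NULL
    root_var <- NULL
  }

  macro_acc <- function(conf) 100 * mean(diag(conf) / rowSums(conf))
  conf_tr <- table(truth = y, predicted = train_pred)
  conf_cv <- table(truth = y, predicted = cv_pred)
  structure(list(
    confusion_train = conf_tr,
    confusion_cv = conf_cv,
    recognition_pct = macro_acc(conf_tr),
    prediction_pct = macro_acc(conf_cv),
    root_scores = roots,
    root_variance_pct = root_var,
    folds = fold,
    seed = seed
  ), class = "lda_cv")
}

#' @export
print.lda_cv <- function(x, ...) {
  cat(sprintf("<lda_cv> recognition %.2f%% | prediction %.2f%% (%d folds)\n",
              x$recognition_pct, x$prediction_pct, max(x$folds)))
  print(x$confusion_cv)
  invisible(x)
}

#' NIPALS partial least squares regression (PLS1)
#'
#' Extracts latent variables by NIPALS deflation: each weight vector
#' maximizes the covariance between X scores and the response, scores are
#' regressed out of both X and y, and the procedure repeats. X and y are
#' centred on the training data (X optionally autoscaled); the weight
#' vector's sign is fixed so its largest-magnitude element is positive,
#' removing NIPALS' sign indeterminacy. Prediction is linear in X.
#'
#' @param X predictor matrix.
#' @param y numeric response vector.
#' @param n_latent number of latent variables, at most
#'   `min(nrow - 1, ncol)`.
#' @param tol convergence tolerance on the score vector.
#' @param max_iter iteration cap per latent variable; exceeded iterations
#'   raise an error naming the component.
#' @param scale_x autoscale X columns (default `FALSE`; the fusion
#'   pipeline scales blocks explicitly).
#' @return list of class `plsr_nipals` with weights `W`, loadings `P`,
#'   y-loadings `q`, scores `T`, regression coefficients for every latent
#'   variable count (`coefs`, a p x n_latent matrix; column a uses a
#'   components) and matching `intercepts`.
#' @export
fit_plsr_nipals <- function(X, y, n_latent, tol = 1e-10, max_iter = 500L,
                            scale_x = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n_latent > min(n - 1L, p))
    stop("n_latent exceeds min(nrow - 1, ncol) = ", min(n - 1L, p))
  x_center <- colMeans(X)
  x_scale <- if (scale_x) apply(X, 2, sd) else rep(1, p)
  if (any(x_scale == 0)) stop("constant column cannot be autoscaled")
  y_center <- mean(y)
  E <- sweep(sweep(X, 2, x_center), 2, x_scale, `/`)
  f <- y - y_center

  W <- matrix(0, p, n_latent); P <- matrix(0, p, n_latent)
  Tm <- matrix(0, n, n_latent); q <- numeric(n_latent)
  a_used <- 0L
  for (a in seq_len(n_latent)) {
    w <- drop(crossprod(E, f))
    if (sqrt(sum(w^2)) < 1e-14) break  # residual exhausted
    t_old <- rep(Inf, n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop("NIPALS did not converge for latent variable ", a)
      w <- w / sqrt(sum(w^2))
      if (w[which.max(abs(w))] < 0) w <- -w
      tt <- drop(E %*% w)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2)) ||
          sum(tt^2) == 0) break
      t_old <- tt
      # univariate y: u = f, so the weight update reproduces w (one pass)
      w <- drop(crossprod(E, f))
    }
    tsq <- sum(tt^2)
    if (tsq == 0) break
    pv <- drop(crossprod(E, tt)) / tsq
    qa <- sum(f * tt) / tsq
    E <- E - tcrossprod(tt, pv)
    f <- f - tt * qa
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- tt; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) {
    coefs <- matrix(0, p, 1L)
    intercepts <- y_center
  } else {
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
    R <- W %*% solve(crossprod(P, W))   # X-space rotation: T = Xc R
    coefs <- vapply(seq_len(a_used), function(a)
      drop(R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]) / x_scale,
      numeric(p))
    coefs <- matrix(coefs, nrow = p)
    intercepts <- y_center - drop(x_center %*% coefs)
  }
  structure(list(W = W, P = P, q = q, T = Tm, n_latent = ncol(coefs),
                 coefs = coefs, intercepts = intercepts,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center),
            class = "plsr_nipals")
}

#' Predict from a NIPALS PLSR model
#'
#' @param object a [fit_plsr_nipals()] model.
#' @param newdata predictor matrix.
#' @param n_latent latent variable count to use (default: all extracted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.plsr_nipals <- function(object, newdata, n_latent = NULL, ...) {
  if (is.null(n_latent)) n_latent <- object$n_latent
  a <- min(n_latent, object$n_latent)
  drop(as.matrix(newdata) %*% object$coefs[, a]) + object$intercepts[a]
}

#' Regression quality metrics
#'
#' RMSE of calibration and cross-validation, coefficients of
#' determination, and the residual prediction deviation
#' RPD = SD(observed) / RMSECV. R-squared uses `1 - SSE/SST` with SST
#' about the mean of `y`; cross-validated R-squared may be negative and
#' is reported unclipped.
#'
#' @param y observed response.
#' @param yhat_train fitted values from the calibration model.
#' @param yhat_cv cross-validated predictions.
#' @return list with `r2_tr`, `rmsec`, `r2_cv`, `rmsecv`, `rpd`, `n_obs`.
#' @export
regression_metrics <- function(y, yhat_train, yhat_cv) {
  stopifnot(length(y) == length(yhat_train), length(y) == length(yhat_cv))
  if (var(y) == 0) stop("response has zero variance")
  sst <- sum((y - mean(y))^2)
  rmse <- function(e) sqrt(mean(e^2))
  rmsec <- rmse(y - yhat_train)
  rmsecv <- rmse(y - yhat_cv)
  list(r2_tr = 1 - sum((y - yhat_train)^2) / sst,
       rmsec = rmsec,
       r2_cv = 1 - sum((y - yhat_cv)^2) / sst,
       rmsecv = rmsecv,
       rpd = sd(y) / rmsecv,
       n_obs = length(y))
}

#' Grouped cross-validated PLSR with latent-variable selection
#'
#' Leave-one-group-out cross-validation where a group is one preparation
#' unit (all scans/repeats of one sample replicate), so no unit ever
#' predicts itself. For every latent-variable count up to `max_latent`
#' the grouped CV predictions are assembled; the final count is the one
#' minimizing RMSECV, and calibration metrics come from a refit on all
#' rows at that count.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param groups group label per row; must partition the rows into at
#'   least 2 groups, none equal to the full data set.
#' @param max_latent maximum latent variables considered; silently capped
#'   at the smallest training-fold size minus one, the column count, and
#'   the number of groups.
#' @param scale_x passed to [fit_plsr_nipals()].
#' @param preproc optional leakage-safe pretreatment hook: a
#'   `function(train_X, test_X)` returning `list(train, test)`, refit on
#'   the training rows of every fold (and on all rows for the final
#'   calibration refit). Used e.g. to fit an MSC reference on training
#'   folds only.
#' @return list of class `plsr_cv` with the [regression_metrics()] fields
#'   plus `n_latent`, `rmsecv_curve`, `cv_pred`, `train_pred`, `groups`.
#' @export
crossval_plsr <- function(X, y, groups, max_latent = 10L, scale_x = FALSE,
                          preproc = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(X), length(y) == nrow(X))
  gs <- unique(groups)
  if (length(gs) < 2) stop("a group equal to the full data set is not a fold")
  min_train <- nrow(X) - max(table(groups))
  A <- min(max_latent, min_train - 1L, ncol(X), length(gs))
  if (A < 1) stop("no latent variables possible with these folds")

  pred <- matrix(NA_real_, nrow(X), A)
  for (g in gs) {
    te <- which(groups == g); tr <- which(groups != g)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (!is.null(preproc)) {
      pp <- preproc(Xtr, Xte)
      Xtr <- pp$train; Xte <- pp$test
    }
    fit <- fit_plsr_nipals(Xtr, y[tr], n_latent = min(A, ncol(Xtr)),
                           scale_x = scale_x)
    for (a in seq_len(A))
      pred[te, a] <- predict(fit, Xte, n_latent = a)
  }
  rmsecv_curve <- apply(pred, 2, function(p) sqrt(mean((y - p)^2)))
  a_opt <- which.min(rmsecv_curve)
  Xfull <- X
  if (!is.null(preproc)) Xfull <- preproc(X, X)$train
  final <- fit_plsr_nipals(Xfull, y, n_latent = a_opt, scale_x = scale_x)
  yhat_tr <- predict(final, Xfull, n_latent = a_opt)
  m <- regression_metrics(y, yhat_tr, pred[, a_opt])
  structure(c(m, list(n_latent = a_opt, rmsecv_curve = rmsecv_curve,
                      cv_pred = pred[, a_opt], train_pred = yhat_tr,
                      groups = groups, model = final)),
            class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat(sprintf(
    "<plsr_cv> %d LV | R2tr %.3f RMSEC %.3f | R2cv %.3f RMSECV %.3f RPD %.2f | n = %d\n",
    x$n_latent, x$r2_tr, x$rmsec, x$r2_cv, x$rmsecv, x$rpd, x$n_obs))
  invisible(x)
}
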