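#' First-difference spectral preprocessing
#'
#' The simplest form of a derivative filter: each variable is subtracted from
#' its immediate neighbour along the ascending wavenumber axis,
#' `out[, j] = X[, j + 1] - X[, j]`, removing the additive part of the signal
#' common to adjacent channels.  `p` channels map to `p - 1` features.
#'
#' @param X numeric matrix, samples in rows, channels in columns (`p >= 2`)
#' @return matrix with `p - 1` columns
#' @export
first_difference <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  assert_that(ncol(X) >= 2, "first difference needs >= 2 channels")
  X[, -1, drop = FALSE] - X[, -ncol(X), drop = FALSE]
}

#' Fit a PLS1 regression (NIPALS)
#'
#' Partial least squares regression for a single response, the standard
#' chemometric calibration tool: latent variables are extracted one at a time
#' as directions in `X` of maximal covariance with `y`, after mean-centering
#' both blocks (no variance scaling, the spectroscopic convention).  For one
#' response the NIPALS weight step is closed-form
#' (`w = X'y / |X'y|`), so the fit is deterministic.
#'
#' @param X predictor matrix, `n` samples x `p` features, all finite
#' @param y numeric response of length `n`
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`
#' @return object of class `pls1`: centering offsets `x_mean`, `y_mean`;
#'   `weights`, `loadings` (`p x n_lv`), y-loadings `q`; scores `n x n_lv`;
#'   `coefficients` list of regression vectors for every component count
#'   `1..n_lv`; `fitted.values` and `residuals` at `n_lv`.
#' @export
pls1 <- function(X, y, n_lv) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  assert_that(n >= 3 && length(y) == n, "need n >= 3 samples with matching y")
  assert_that(all(is.finite(X)) && all(is.finite(y)), "X and y must be finite",
              "scanstab_data_error")
  if (stats::var(y) == 0)
    stop_scanstab("response has zero variance", "scanstab_degenerate_response_error")
  assert_that(n_lv >= 1 && n_lv <= min(n - 1, p),
              sprintf("n_lv must be in 1..%d", min(n - 1, p)))

  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)            # deflated X residual
  f <- y - y_mean                     # deflated y residual
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  k_used <- 0
  for (k in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break             # X residual carries no covariance with y
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pk <- drop(crossprod(E, t)) / tt
    qk <- sum(f * t) / tt
    E <- E - tcrossprod(t, pk)
    f <- f - qk * t
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- t; q[k] <- qk
    k_used <- k
  }
  assert_that(k_used >= 1, "no usable latent variable (X uncorrelated with y)",
              "scanstab_degenerate_response_error")
  W <- W[, seq_len(k_used), drop = FALSE]
  P <- P[, seq_len(k_used), drop = FALSE]
  Tm <- Tm[, seq_len(k_used), drop = FALSE]
  q <- q[seq_len(k_used)]

  ## regression vector for every component count: b_k = W_k (P_k' W_k)^-1 q_k
  coefs <- vector("list", k_used)
  for (k in seq_len(k_used)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    coefs[[k]] <- drop(Wk %*% solve(crossprod(Pk, Wk), q[seq_len(k)]))
  }
  fitted <- y_mean + drop(sweep(X, 2, x_mean) %*% coefs[[k_used]])
  structure(list(n_lv = k_used, n_lv_requested = n_lv,
                 x_mean = x_mean, y_mean = y_mean,
                 weights = W, loadings = P, scores = Tm, q = q,
                 coefficients = coefs,
                 fitted.values = fitted, residuals = y - fitted,
                 y = y, n = n, p = p),
            class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1> %d latent variable(s), n = %d, p = %d\n",
              x$n_lv, x$n, x$p))
  cat(sprintf("  training RMS error: %.6g\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.pls1 <- function(object, n_lv = object$n_lv, ...) {
  b <- object$coefficients[[n_lv]]
  c(`(Intercept)` = object$y_mean - sum(object$x_mean * b), b)
}

#' Predict from a fitted PLS1 model
#'
#' @param object a [pls1()] fit
#' @param newdata matrix with the model's feature count (after any
#'   preprocessing applied before fitting)
#' @param n_lv number of components to use (default: all fitted)
#' @param ... ignored
#' @return numeric predictions `y_mean + (X - x_mean) b`
#' @export
predict.pls1 <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  assert_that(ncol(newdata) == object$p,
              sprintf("newdata has %d features; model expects %d",
                      ncol(newdata), object$p))
  assert_that(n_lv >= 1 && n_lv <= object$n_lv, "n_lv out of fitted range")
  object$y_mean + drop(sweep(newdata, 2, object$x_mean) %*%
                         object$coefficients[[n_lv]])
}

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' Leave-one-out cross-validation of a PLS1 calibration
#'
#' For every candidate component count `1..max_lv`, each sample is predicted
#' by a model fitted on the other `n - 1` (centering recomputed inside each
#' fold, so the held-out sample never leaks into the fit).  The component
#' count minimizing RMSECV is chosen, ties going to the smaller count.
#' Figures of merit at the chosen count: `RMSECV = sqrt(mean((y - yhat_cv)^2))`
#' and `R2 = 1 - PRESS / TSS`, the coefficient of determination of the
#' cross-validated predictions; the squared Pearson correlation between `y`
#' and `yhat_cv` is reported alongside.
#'
#' @param X predictor matrix (`n >= 5`)
#' @param y response vector
#' @param max_lv largest component count tried (capped at `min(max_lv, n - 2,
#'   p)`)
#' @return object of class `pls_loocv`: `n_lv` (chosen), `rmsecv`, `r2`,
#'   `r2_pearson`, `rmsecv_by_lv`, `cv_pred` (held-out predictions at the
#'   chosen count), `cv_pred_by_lv` (n x max_lv matrix), `y`, and an
#'   `outlier` flag marking `|CV residual| > 3 RMSECV`.
#' @export
pls_loocv <- function(X, y, max_lv = 10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  assert_that(n >= 5, "LOOCV needs n >= 5")
  K <- min(max_lv, n - 2, ncol(X))
  assert_that(K >= 1, "no admissible component count")
  if (stats::var(y) == 0)
    stop_scanstab("response has zero variance", "scanstab_degenerate_response_error")

  cv_pred <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    fit <- pls1(X[-i, , drop = FALSE], y[-i], n_lv = K)
    for (k in seq_len(fit$n_lv))
      cv_pred[i, k] <- predict(fit, X[i, , drop = FALSE], n_lv = k)
    if (fit$n_lv < K)                      # rank-deficient fold: reuse deepest
      cv_pred[i, (fit$n_lv + 1):K] <- cv_pred[i, fit$n_lv]
  }
  rmsecv_by_lv <- sqrt(colMeans((cv_pred - y)^2))
  n_lv <- which.min(rmsecv_by_lv)          # ties resolve to fewer components
  yhat <- cv_pred[, n_lv]
  press <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  rmsecv <- sqrt(press / n)
  structure(list(n_lv = n_lv, rmsecv = rmsecv,
                 r2 = 1 - press / tss,
                 r2_pearson = stats::cor(y, yhat)^2,
                 rmsecv_by_lv = rmsecv_by_lv,
                 cv_pred = yhat, cv_pred_by_lv = cv_pred, y = y,
                 outlier = abs(y - yhat) > 3 * rmsecv,
                 n = n, max_lv = K),
            class = "pls_loocv")
}

#' @export
print.pls_loocv <- function(x, ...) {
  cat(sprintf("<pls_loocv> n = %d | chosen LVs = %d | RMSECV = %.4g | R2 = %.4f\n",
              x$n, x$n_lv, x$rmsecv, x$r2))
  if (any(x$outlier))
    cat(sprintf("  flagged CV outliers (|resid| > 3 RMSECV): %s\n",
                paste(which(x$outlier), collapse = ", ")))
  invisible(x)
}
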