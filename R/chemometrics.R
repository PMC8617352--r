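# PLS2 regression by NIPALS with segmented cross-validation,
# latent-variable selection, model metrics and small multivariate
# utilities (PCA, Pearson correlation with significance).

#' Fit a PLS2 regression model (NIPALS)
#'
#' Mean-centres `X` and `Y` (no variance scaling by default), then
#' extracts latent variables by the NIPALS algorithm: per component, a
#' weight vector along the dominant X'Y covariance direction, the score
#' `t = Xw`, X-loadings `p` and Y-loadings `q`, deflating both blocks
#' by the rank-one score contribution. The regression-coefficient
#' matrix is `beta = W (P'W)^-1 Q'`.
#'
#' If a weight vector degenerates to zero norm (X exhausted), the fit
#' stops early and reports the achieved number of components.
#'
#' @param X n x p predictor matrix (no missing values).
#' @param Y n x q response matrix or length-n vector.
#' @param n_lv Number of latent variables requested.
#' @param scale_y Autoscale responses to unit variance before fitting
#'   (coefficients and predictions are back-transformed); default off.
#' @param wavelengths Optional per-predictor wavelengths stored for
#'   [regression_vector()].
#' @param tol NIPALS convergence tolerance on the score vector.
#' @return A `pls_model` with centering vectors, weights `W`, loadings
#'   `P` and `Q`, scores `T`, per-component coefficient array and the
#'   final `beta`.
#' @export
fit_pls2 <- function(X, Y, n_lv, scale_y = FALSE, wavelengths = NULL,
                     tol = 1e-10) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) stop("missing values are not supported")
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y row counts differ")
  if (n_lv < 1) stop("n_lv must be >= 1")
  if (n <= n_lv) stop("need more samples than latent variables")
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  y_scale <- if (scale_y) apply(Y, 2, stats::sd) else rep(1, ncol(Y))
  if (any(y_scale == 0)) stop("cannot autoscale a constant response")
  E <- sweep(X, 2, x_mean)
  Fm <- sweep(sweep(Y, 2, y_mean), 2, y_scale, "/")
  p <- ncol(E); q <- ncol(Fm)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, q, n_lv); Tm <- matrix(0, n, n_lv)
  a <- 0
  for (k in seq_len(n_lv)) {
    u <- Fm[, which.max(apply(Fm, 2, stats::var))]
    if (sum(u^2) == 0) break
    t_old <- rep(Inf, n)
    for (it in seq_len(500)) {
      w <- crossprod(E, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-14) break
      w <- w / wn
      tt <- E %*% w
      qv <- crossprod(Fm, tt) / sum(tt^2)
      if (q > 1) u <- Fm %*% qv / sum(qv^2) else u <- Fm[, 1]
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
      if (q == 1) break  # single response: one pass is exact
    }
    w <- crossprod(E, u)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break
    w <- w / wn
    tt <- E %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-28) break
    pv <- crossprod(E, tt) / tt2
    qv <- crossprod(Fm, tt) / tt2
    E <- E - tt %*% t(pv)
    Fm <- Fm - tt %*% t(qv)
    a <- k
    W[, k] <- w; P[, k] <- pv; Q[, k] <- qv; Tm[, k] <- tt
  }
  if (a == 0) stop("rank-deficient problem: no latent variable extracted")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[, seq_len(a), drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
  # cumulative coefficients at 1..a components, on the original Y scale
  beta_lv <- array(0, c(p, q, a))
  for (k in seq_len(a)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    Qk <- Q[, seq_len(k), drop = FALSE]
    Bk <- Wk %*% solve(crossprod(Pk, Wk), t(Qk))
    beta_lv[, , k] <- sweep(Bk, 2, y_scale, "*")
  }
  structure(list(x_mean = x_mean, y_mean = y_mean, y_scale = y_scale,
                 x_weights = W, x_loadings = P, y_loadings = Q,
                 scores = Tm, n_lv = a, n_lv_requested = n_lv,
                 beta = beta_lv[, , a, drop = TRUE],
                 beta_lv = beta_lv,
                 wavelengths = wavelengths,
                 response_names = colnames(Y)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d predictors, %d responses\n",
              x$n_lv, nrow(x$x_weights), nrow(x$y_loadings)))
  invisible(x)
}

#' Predict from a PLS2 model
#' @param object A `pls_model`.
#' @param newdata Matrix on the model's band grid and pre-treatment.
#' @param n_lv Components used (default: all fitted).
#' @param ... Unused.
#' @return n x q matrix of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("alignment error: newdata has ", ncol(newdata),
         " predictors, model expects ", length(object$x_mean))
  if (n_lv < 1 || n_lv > object$n_lv)
    stop("n_lv must be in 1..", object$n_lv)
  B <- object$beta_lv[, , n_lv]
  if (is.null(dim(B))) B <- matrix(B, ncol = length(object$y_mean))
  out <- sweep(newdata, 2, object$x_mean) %*% B
  sweep(out, 2, object$y_mean, "+")
}

#' Cross-validation plan with balanced, batch-stratified segments
#'
#' Assigns every bean to one of `n_segments` held-out segments.
#' Assignment shuffles beans within each batch and deals them
#' round-robin across segments, so segment sizes differ by at most one
#' and each segment samples across batches.
#'
#' @param bean_ids Character vector of bean identifiers.
#' @param n_segments Number of segments (default 20).
#' @param batch Optional batch factor for stratification.
#' @param seed Integer seed for the assignment permutation.
#' @return A `cv_plan`: list with `n_segments` and integer `assignment`
#'   named by bean.
#' @export
cv_plan <- function(bean_ids, n_segments = 20, batch = NULL, seed = 1L) {
  n <- length(bean_ids)
  if (n_segments < 2 || n_segments > n)
    stop("plan error: need 2 <= n_segments <= n")
  if (anyDuplicated(bean_ids)) stop("bean_ids must be unique")
  set.seed(seed)
  if (is.null(batch)) {
    ord <- sample.int(n)
  } else {
    # shuffle within batch, concatenate batches: round-robin dealing then
    # spreads every batch across segments
    idx <- seq_len(n)
    ord <- unlist(lapply(split(idx, batch), function(ii) ii[sample.int(length(ii))]),
                  use.names = FALSE)
  }
  assignment <- integer(n)
  assignment[ord] <- rep_len(seq_len(n_segments), n)
  names(assignment) <- bean_ids
  structure(list(n_segments = n_segments, assignment = assignment,
                 seed = seed), class = "cv_plan")
}

#' Segmented cross-validation of a PLS2 model
#'
#' For each segment, refits on the remaining beans (centering recomputed
#' per fold; pre-treatments are per-spectrum so no statistics leak) and
#' predicts the held-out segment at every component count. Held-out
#' predictions are pooled before computing RMSECV and cross-validated
#' R2 (coefficient of determination, `1 - SSE/SST`).
#'
#' @param X n x p pre-treated spectra.
#' @param Y n x q responses (or vector).
#' @param lv_max Largest component count evaluated; reduced if a
#'   training fold cannot support it.
#' @param plan A [cv_plan()].
#' @param scale_y Passed to [fit_pls2()].
#' @return List with `rmsecv` and `r2cv` (lv_max x q matrices),
#'   `predictions` (n x q x lv_max array of pooled held-out
#'   predictions) and `lv_max`.
#' @export
cross_validate <- function(X, Y, lv_max, plan, scale_y = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (length(plan$assignment) != n)
    stop("plan error: plan covers ", length(plan$assignment),
         " beans, data has ", n)
  seg <- plan$assignment
  min_train <- n - max(tabulate(seg, plan$n_segments))
  lv_max <- min(lv_max, min_train - 1, ncol(X))
  if (lv_max < 1) stop("plan error: training folds too small")
  preds <- array(NA_real_, c(n, ncol(Y), lv_max))
  for (s in seq_len(plan$n_segments)) {
    hold <- which(seg == s)
    if (length(hold) == 0) next
    fit <- fit_pls2(X[-hold, , drop = FALSE], Y[-hold, , drop = FALSE],
                    n_lv = lv_max, scale_y = scale_y)
    for (k in seq_len(fit$n_lv))
      preds[hold, , k] <- predict(fit, X[hold, , drop = FALSE], n_lv = k)
    if (fit$n_lv < lv_max)  # rank-deficient fold: reuse deepest model
      for (k in seq(fit$n_lv + 1, lv_max))
        preds[hold, , k] <- preds[hold, , fit$n_lv]
  }
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  rmsecv <- matrix(0, lv_max, ncol(Y))
  r2cv <- matrix(0, lv_max, ncol(Y))
  for (k in seq_len(lv_max)) {
    err <- Y - preds[, , k]
    rmsecv[k, ] <- sqrt(colMeans(err^2))
    r2cv[k, ] <- 1 - colSums(err^2) / sst
  }
  colnames(rmsecv) <- colnames(r2cv) <- colnames(Y)
  list(rmsecv = rmsecv, r2cv = r2cv, predictions = preds, lv_max = lv_max)
}

#' Parsimonious latent-variable selection
#'
#' Averages the RMSECV curve over responses and returns the smallest
#' component count whose averaged RMSECV is within `tolerance` of the
#' global minimum — the "lowest possible" rule that trades a marginal
#' error increase for robustness against over-fitting.
#'
#' @param cv Result of [cross_validate()], or an RMSECV matrix/vector.
#' @param tolerance Relative slack above the minimum (default 0.02).
#' @return Selected number of latent variables.
#' @export
select_lv <- function(cv, tolerance = 0.02) {
  rmse <- if (is.list(cv)) cv$rmsecv else cv
  rmse <- as.matrix(rmse)
  if (nrow(rmse) == 0) stop("empty cross-validation curve")
  m <- rowMeans(rmse)
  which(m <= (1 + tolerance) * min(m))[1]
}

#' Calibration/validation metrics per response
#'
#' @param y_ref n x q reference values (or vector).
#' @param y_hat_cal Training predictions.
#' @param y_hat_cv Pooled cross-validated predictions.
#' @return data.frame with one row per response: `r2_cal`, `rmse_cal`,
#'   `r2_cv`, `rmse_cv` and `rpd` (reference SD over RMSECV; `Inf` for
#'   perfect cross-validated predictions).
#' @export
compute_metrics <- function(y_ref, y_hat_cal, y_hat_cv) {
  y_ref <- as.matrix(y_ref); y_hat_cal <- as.matrix(y_hat_cal)
  y_hat_cv <- as.matrix(y_hat_cv)
  stopifnot(all(dim(y_ref) == dim(y_hat_cal)),
            all(dim(y_ref) == dim(y_hat_cv)))
  sds <- apply(y_ref, 2, stats::sd)
  if (any(sds == 0)) stop("metric error: zero-variance reference")
  one <- function(y, yhat) {
    sse <- sum((y - yhat)^2)
    sst <- sum((y - mean(y))^2)
    c(r2 = 1 - sse / sst, rmse = sqrt(mean((y - yhat)^2)))
  }
  out <- data.frame(response = colnames(y_ref) %||%
                      paste0("y", seq_len(ncol(y_ref))))
  for (j in seq_len(ncol(y_ref))) {
    cal <- one(y_ref[, j], y_hat_cal[, j])
    cvm <- one(y_ref[, j], y_hat_cv[, j])
    out$r2_cal[j] <- cal["r2"]; out$rmse_cal[j] <- cal["rmse"]
    out$r2_cv[j] <- cvm["r2"]; out$rmse_cv[j] <- cvm["rmse"]
    out$rpd[j] <- if (cvm["rmse"] == 0) Inf else sds[j] / cvm["rmse"]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regression vector of one response
#'
#' The per-wavelength PLS coefficients, used to inspect which
#' absorption bands drive a prediction.
#'
#' @param model A `pls_model` fitted with `wavelengths`.
#' @param response Response name or column index.
#' @param n_lv Components used (default: all fitted).
#' @return data.frame with `wavelength` (if known) and `coefficient`.
#' @export
regression_vector <- function(model, response = 1, n_lv = model$n_lv) {
  stopifnot(inherits(model, "pls_model"))
  q <- nrow(model$y_loadings)
  j <- if (is.character(response)) {
    if (is.null(model$response_names) || !(response %in% model$response_names))
      stop("lookup error: unknown response '", response, "'")
    match(response, model$response_names)
  } else {
    if (response < 1 || response > q)
      stop("lookup error: response index out of range")
    response
  }
  B <- model$beta_lv[, , n_lv]
  if (is.null(dim(B))) B <- matrix(B, ncol = q)
  data.frame(wavelength = model$wavelengths %||%
               seq_len(nrow(model$x_weights)),
             coefficient = B[, j])
}

#' Principal component analysis (centred SVD)
#' @param X n x p matrix.
#' @param n_components Number of components returned.
#' @return List with `scores`, `loadings` and `explained_variance`
#'   (fractions, decreasing, summing to <= 1).
#' @export
pca <- function(X, n_components) {
  X <- as.matrix(X)
  if (n_components < 1 || n_components > min(dim(X)))
    stop("dimension error: n_components must be in 1..min(dim(X))")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[k])
}

#' Pearson correlation matrix with two-sided p-values
#'
#' p-values come from the t transform `t = r sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom. Constant columns yield `NA`
#' correlations and are flagged.
#'
#' @param Y n x q matrix, n >= 3.
#' @return List with `r`, `p` (q x q matrices) and `undefined`
#'   (logical per column, TRUE where the column is constant).
#' @export
pearson_matrix <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 3) stop("need at least 3 observations")
  constant <- apply(Y, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(Y))
  r[constant, ] <- NA; r[, constant] <- NA
  diag(r)[!constant] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  list(r = r, p = p, n = n, undefined = constant)
}
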