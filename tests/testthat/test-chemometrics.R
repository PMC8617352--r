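test_that("PLS2 recovers an exact linear relation at the true rank", {
  set.seed(1)
  X <- matrix(stats::rnorm(30 * 6), 30, 6)
  B <- matrix(stats::rnorm(6 * 3), 6, 3)
  Y <- X %*% B
  fit <- fit_pls2(X, Y, n_lv = 6)
  Yhat <- predict(fit, X)
  for (j in 1:3) {
    r2 <- 1 - sum((Y[, j] - Yhat[, j])^2) / sum((Y[, j] - mean(Y[, j]))^2)
    expect_equal(r2, 1, tolerance = 1e-10)
  }
})

test_that("PLS2 at full rank equals the least-squares solution", {
  set.seed(2)
  worst <- 0
  for (rep in 1:20) {
    X <- matrix(stats::rnorm(20 * 5), 20, 5)
    Y <- X %*% matrix(stats::rnorm(5 * 2), 5, 2) +
      matrix(stats::rnorm(40, 0, 0.2), 20, 2)
    fit <- fit_pls2(X, Y, n_lv = 5)
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    b_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
    worst <- max(worst, max(abs(fit$beta - b_ols)))
  }
  expect_lt(worst, 1e-8)
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(3)
  X <- matrix(stats::rnorm(50 * 12), 50, 12)
  Y <- matrix(stats::rnorm(50 * 4), 50, 4)
  fit <- fit_pls2(X, Y, n_lv = 8)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("prediction respects centering and training consistency", {
  set.seed(4)
  X <- matrix(stats::rnorm(40 * 10), 40, 10)
  Y <- X[, 1:2] %*% matrix(c(1, 2, -1, 0.5), 2, 2) +
    matrix(stats::rnorm(80, 0, 0.1), 40, 2)
  colnames(Y) <- c("a", "b")
  fit <- fit_pls2(X, Y, n_lv = 4)
  # the mean spectrum predicts the mean response
  expect_equal(as.vector(predict(fit, rbind(fit$x_mean))),
               unname(fit$y_mean), tolerance = 1e-10)
  # alignment error on a mismatched band grid
  expect_error(predict(fit, X[, 1:5]), "alignment error")
})

test_that("SNV pretreatment makes predictions invariant to scatter", {
  # affine distortion of reflectance-derived absorbance is removed by
  # SNV, so predictions from SNV-pretreated spectra do not change
  set.seed(5)
  wl <- seq(1000, 2000, length.out = 50)
  A <- 0.5 + matrix(stats::rnorm(30 * 50, 0, 0.1), 30, 50)
  R <- 10^(-A)
  spec <- pretreat_spec("snv")
  X <- pretreat_matrix(R, wl, spec)
  Y <- X[, 3] + stats::rnorm(30, 0, 0.05)
  fit <- fit_pls2(X, Y, n_lv = 3)
  # distort each spectrum with its own gain and offset in absorbance
  gains <- stats::runif(30, 0.8, 1.2); offs <- stats::rnorm(30, 0, 0.2)
  R_dist <- 10^(-(sweep(sweep(A, 1, gains, "*"), 1, offs, "+")))
  X_dist <- pretreat_matrix(R_dist, wl, spec)
  expect_equal(predict(fit, X_dist), predict(fit, X), tolerance = 1e-10)
})

test_that("cv_plan partitions beans into near-equal batch-spread segments", {
  ids <- sprintf("bean%03d", 1:250)
  batch <- rep(1:25, each = 10)
  plan <- cv_plan(ids, n_segments = 20, batch = batch, seed = 9)
  sizes <- tabulate(plan$assignment, 20)
  expect_setequal(unique(sizes), c(12, 13))
  expect_equal(sum(sizes), 250)
  # every segment draws from several batches
  spread <- sapply(1:20, function(s)
    length(unique(batch[plan$assignment == s])))
  expect_true(all(spread >= 5))
  expect_error(cv_plan(ids, n_segments = 300), "plan error")
})

test_that("cross-validation drives RMSECV to zero on noiseless low-rank data", {
  set.seed(6)
  n <- 60
  S <- matrix(stats::rnorm(n * 3), n, 3)
  X <- S %*% matrix(stats::rnorm(3 * 20), 3, 20)
  Y <- S %*% matrix(stats::rnorm(3 * 2), 3, 2)
  plan <- cv_plan(sprintf("b%02d", 1:n), n_segments = 10, seed = 2)
  cv <- cross_validate(X, Y, lv_max = 5, plan)
  expect_lt(max(cv$rmsecv[3, ]), 1e-6)
})

test_that("pure-noise responses never cross-validate well (no leakage)", {
  set.seed(7)
  worst <- -Inf
  for (rep in 1:50) {
    X <- matrix(stats::rnorm(100 * 20), 100, 20)
    y <- stats::rnorm(100)
    plan <- cv_plan(sprintf("b%03d", 1:100), n_segments = 10, seed = rep)
    cv <- cross_validate(X, y, lv_max = 5, plan)
    worst <- max(worst, max(cv$r2cv))
  }
  expect_lte(worst, 0.1)
})

test_that("permuting responses destroys CV performance but not training fit", {
  st <- simulate_study(sim_config(n_batches = 10, beans_per_batch = 10,
                                  seed = 13))
  X <- study_design_matrix(st)
  Y <- response_matrix(st$profiles, target_sets = "class")[, "Pyrazine"]
  set.seed(99)
  Yp <- sample(Y)
  plan <- cv_plan(rownames(X), n_segments = 20,
                  batch = st$chemistry$meta$batch_id, seed = 1)
  cv <- cross_validate(X, Yp, lv_max = 15, plan)
  expect_lte(max(cv$r2cv), 0.1)
  fit <- fit_pls2(X, Yp, n_lv = 15)
  yhat <- predict(fit, X)
  r2_train <- 1 - sum((Yp - yhat)^2) / sum((Yp - mean(Yp))^2)
  expect_gt(r2_train, 0.5)
})

test_that("latent-variable selection follows the parsimony rule", {
  # flattens after 11 within 2%
  curve1 <- c(10, 8, 6, 5, 4, 3, 2.5, 2, 1.7, 1.5, 1.40, 1.39, 1.385, 1.38)
  expect_equal(select_lv(curve1, tolerance = 0.02), 11)
  # monotone increasing
  expect_equal(select_lv(seq(1, 2, by = 0.1)), 1)
  # global min at 17 but 11 within 2%
  curve3 <- c(seq(5, 1.02, length.out = 11), rep(1.015, 5), 1.0, 1.01)
  expect_equal(select_lv(curve3, tolerance = 0.02), 11)
})

test_that("metrics follow their definitions including the RPD identity", {
  set.seed(8)
  y <- stats::rnorm(50, 10, 2)
  # perfect predictions
  m <- compute_metrics(y, y, y)
  expect_equal(m$r2_cal, 1); expect_equal(m$rmse_cv, 0)
  expect_equal(m$rpd, Inf)
  # constant mean predictor
  ybar <- rep(mean(y), 50)
  m <- compute_metrics(y, ybar, ybar)
  expect_equal(m$r2_cv, 0)
  expect_equal(m$rpd, sqrt(50 / 49), tolerance = 1e-12)
  # rmse_cv = sd/2 gives RPD exactly 2
  resid <- stats::rnorm(50); resid <- resid - mean(resid)
  resid <- resid / sqrt(mean(resid^2)) * stats::sd(y) / 2
  m <- compute_metrics(y, y, y + resid)
  expect_equal(m$rpd, 2, tolerance = 1e-12)
  # identity rpd * rmse_cv / sd = 1 on arbitrary prediction sets
  yhat <- y + stats::rnorm(50, 0, 0.5)
  m <- compute_metrics(y, yhat, yhat)
  expect_equal(m$rpd * m$rmse_cv / stats::sd(y), 1, tolerance = 1e-9)
  expect_error(compute_metrics(rep(1, 5), rep(1, 5), rep(1, 5)),
               "metric error")
})

test_that("regression vectors localize an informative band", {
  set.seed(14)
  hits <- 0
  for (rep in 1:50) {
    n <- 40; p <- 60
    X <- matrix(stats::rnorm(n * p), n, p)
    informative <- sample(5:(p - 5), 1)
    y <- 2 * X[, informative] + stats::rnorm(n, 0, 0.3)
    fit <- fit_pls2(X, y, n_lv = 3, wavelengths = seq_len(p) * 10 + 900)
    rv <- regression_vector(fit, 1)
    peak <- which.max(abs(rv$coefficient))
    if (abs(peak - informative) <= 2) hits <- hits + 1
  }
  expect_gt(hits, 25)  # majority criterion
})

test_that("anti-correlated targets yield anti-correlated regression vectors", {
  set.seed(15)
  n <- 60; p <- 40
  X <- matrix(stats::rnorm(n * p), n, p)
  base <- as.vector(X %*% stats::rnorm(p, 0, 0.3))
  Y <- cbind(ald = base + stats::rnorm(n, 0, 0.1),
             pyr = -base + stats::rnorm(n, 0, 0.1))
  fit <- fit_pls2(X, Y, n_lv = 5)
  va <- regression_vector(fit, "ald")$coefficient
  vp <- regression_vector(fit, "pyr")$coefficient
  cosine <- sum(va * vp) / sqrt(sum(va^2) * sum(vp^2))
  expect_lt(cosine, 0)
  expect_error(regression_vector(fit, "nope"), "lookup error")
})

test_that("PCA is a centred SVD with the expected algebraic properties", {
  set.seed(16)
  # rank-2 data: two components explain everything
  S <- matrix(stats::rnorm(30 * 2), 30, 2)
  X <- S %*% matrix(stats::rnorm(2 * 8), 2, 8)
  p2 <- pca(X, 2)
  expect_equal(sum(p2$explained_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(p2$explained_variance) <= 0))
  # scores covariance is diagonal
  Xf <- matrix(stats::rnorm(40 * 6), 40, 6)
  pf <- pca(Xf, 6)
  cv <- stats::cov(pf$scores)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-10)
  # full-rank reconstruction
  Xc <- scale(Xf, scale = FALSE)
  expect_lt(max(abs(pf$scores %*% t(pf$loadings) - Xc)), 1e-8)
  expect_error(pca(Xf, 10), "dimension error")
})

test_that("Pearson matrix reports exact correlations and flags constants", {
  set.seed(17)
  y <- stats::rnorm(30)
  Y <- cbind(a = y, b = -y, c = stats::rnorm(30), d = rep(1, 30))
  pm <- pearson_matrix(Y)
  expect_equal(pm$r["a", "b"], -1)
  expect_equal(pm$r["a", "a"], 1)
  expect_true(pm$undefined["d"])
  expect_true(is.na(pm$r["a", "d"]))
  # p-value agrees with cor.test
  ct <- stats::cor.test(Y[, "a"], Y[, "c"])
  expect_equal(pm$p["a", "c"], ct$p.value, tolerance = 1e-12)
  expect_error(pearson_matrix(Y[1:2, ]), "at least 3")
})
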