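# Standardization, PLSR fitting/projection/prediction, component grid
# search and the full linear baseline.

test_that("zscore_columns standardizes, is idempotent and rejects constants", {
  z <- zscore_columns(matrix(c(1, 2, 3), 3, 1), ddof = 1)
  expect_equal(as.numeric(z$values), c(-1, 0, 1))  # hand computation
  expect_equal(z$params$means, 2, ignore_attr = TRUE)
  expect_equal(z$params$sds, 1, ignore_attr = TRUE)

  set.seed(1)
  m <- matrix(rnorm(40), 10, 4)
  z1 <- zscore_columns(m)$values
  expect_equal(colMeans(z1), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(z1, 2, sd), rep(1, 4), tolerance = 1e-12)
  expect_equal(zscore_columns(z1)$values, z1, tolerance = 1e-12)  # idempotence

  # ddof = 0 population convention
  z0 <- zscore_columns(m, ddof = 0)$values
  expect_equal(sqrt(colMeans(sweep(z0, 2, colMeans(z0))^2)), rep(1, 4),
               tolerance = 1e-12)

  bad <- m
  bad[, 2] <- 5
  colnames(bad) <- paste0("f", 1:4)
  expect_error(zscore_columns(bad), "f2")
})

test_that("PLSR matches the textbook NIPALS oracle on seeded random instances", {
  set.seed(2)
  for (rep in 1:10) {
    X <- scale(matrix(rnorm(40), 10, 4))
    Y <- scale(matrix(rnorm(30), 10, 3))
    fit <- fit_plsr(X, Y, 2)
    oracle <- nipals_pls2_oracle(X, Y, 2)
    expect_equal(fit$x_weights, oracle$W, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$x_loadings, oracle$P, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$y_loadings, oracle$Q, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$train_scores, oracle$T, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$x_rotation, oracle$R, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("PLSR model invariants hold", {
  set.seed(3)
  X <- scale(matrix(rnorm(480 * 66), 480, 66))
  Y <- scale(matrix(rnorm(480 * 50), 480, 50))
  fit <- fit_plsr(X, Y, 5)
  # reported loading shapes
  expect_equal(dim(fit$x_loadings), c(66L, 5L))
  expect_equal(dim(fit$y_loadings), c(50L, 5L))
  # scores reproduce from the rotation
  expect_equal(max(abs(X %*% fit$x_rotation - fit$train_scores)), 0,
               tolerance = 1e-8)
  # training predictions equal scores times y-loadings
  expect_equal(unclass(predict_responses(fit, X)),
               fit$train_scores %*% t(fit$y_loadings), tolerance = 1e-8,
               ignore_attr = TRUE)
  # successive training scores mutually orthogonal
  cc <- abs(cor(fit$train_scores))
  expect_lt(max(cc - diag(5)), 1e-8)
  # sign convention: largest-magnitude x-weight entry positive
  for (h in 1:5) {
    w <- fit$x_weights[, h]
    expect_gt(w[which.max(abs(w))], 0)
  }
  # training R^2 non-decreasing in k
  r2k <- sapply(1:5, function(k) {
    f <- fit_plsr(X, Y, k)
    mean(r2_map(Y, unclass(predict_responses(f, X)))$values)
  })
  expect_true(all(diff(r2k) > -1e-10))
})

test_that("noise-free rank-2 latent data are reproduced exactly", {
  # rank-2 stimulus block (noise-free latent model): two components give an
  # exact training fit, and held-out responses are predicted exactly
  set.seed(4)
  Z <- matrix(rnorm(40 * 2), 40, 2)
  A <- matrix(rnorm(12), 6, 2)
  X <- Z %*% t(A)
  C <- matrix(rnorm(10), 2, 5)
  Y <- Z %*% C
  fit <- fit_plsr(X[1:30, ], Y[1:30, ], 2)
  expect_equal(unclass(predict_responses(fit, X[1:30, ])), Y[1:30, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unclass(predict_responses(fit, X[31:40, ])), Y[31:40, ],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(fit_plsr(X, Y, 0), "k must be >= 1")
  expect_error(fit_plsr(X, Y, 3), "rank")
})

test_that("latent projection follows the rotation and is linear", {
  set.seed(5)
  X <- scale(matrix(rnorm(50 * 8), 50, 8))
  Y <- scale(matrix(rnorm(50 * 10), 50, 10))
  fit <- fit_plsr(X, Y, 3)
  # projecting the training data reproduces training scores
  expect_equal(unclass(project_latent(fit, X)), fit$train_scores,
               tolerance = 1e-8, ignore_attr = TRUE)
  # direct matrix oracle on new data
  Xnew <- matrix(rnorm(16), 2, 8)
  oracle <- Xnew %*% fit$x_weights %*%
    solve(t(fit$x_loadings) %*% fit$x_weights)
  expect_equal(unclass(project_latent(fit, Xnew)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero row maps to zero scores
  expect_equal(unclass(project_latent(fit, matrix(0, 1, 8))),
               matrix(0, 1, 3), ignore_attr = TRUE)
  # prediction is the projection composed with the y-loadings
  expect_equal(unclass(predict_responses(fit, Xnew)),
               unclass(project_latent(fit, Xnew)) %*% t(fit$y_loadings),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(project_latent(fit, matrix(0, 1, 5)), "feature count")
})

test_that("component grid search recovers the latent dimensionality", {
  cfg <- generator_config(n_concepts = 240, n_stim_dims = 20, k_true = 3,
                          subdivisions = 2, snr = 5, seed = 17)
  ds <- generate_dataset(cfg)
  gs <- grid_search_components(ds$X, ds$Y$values, k_range = 1:5, seed = 2)
  expect_equal(gs$selected_k, 3L)
  expect_equal(nrow(gs$results), 5L)
  expect_equal(gs$n_folds, 5L)
  # curve rises to k_true then flattens
  m <- gs$results$mean_max_r2
  expect_true(all(diff(m[1:3]) > 0))
  expect_lt(max(abs(diff(m[3:5]))), 0.01)
  # degenerate range
  g1 <- grid_search_components(ds$X, ds$Y$values, k_range = 1, seed = 2)
  expect_equal(g1$selected_k, 1L)
  expect_error(grid_search_components(ds$X, ds$Y$values, integer(0)),
               "non-empty")
})

test_that("the linear baseline matches normal equations and is nested in PLSR", {
  set.seed(6)
  X <- scale(matrix(rnorm(40 * 5), 40, 5))
  Y <- scale(matrix(rnorm(40 * 7), 40, 7))
  lin <- fit_linear_baseline(X, Y)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(lin$coefficients, oracle, tolerance = 1e-8, ignore_attr = TRUE)

  # noise-free linear responses are predicted perfectly out of sample
  C <- matrix(rnorm(35), 5, 7)
  Ylin <- X %*% C
  Xte <- scale(matrix(rnorm(20 * 5), 20, 5))
  lin2 <- fit_linear_baseline(X, Ylin)
  r2 <- r2_map(Xte %*% C, predict_linear(lin2, Xte))
  expect_equal(r2$values, rep(1, 7), tolerance = 1e-6)

  # PLSR with k = p reproduces the baseline's training predictions
  fit <- fit_plsr(X, Y, 5)
  expect_equal(unclass(predict_responses(fit, X)),
               unclass(predict_linear(lin, X)), tolerance = 1e-6,
               ignore_attr = TRUE)

  # rank-deficient design is refused
  Xdef <- cbind(X, X[, 1])
  expect_error(fit_linear_baseline(Xdef, Y), "rank-deficient")
})
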