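# GLM reproducibility, mirror transport, symmetry, loading agreement and
# property correlations.

test_that("the held-out GLM recovers exact loadings and matches normal equations", {
  set.seed(30)
  L <- matrix(rnorm(30 * 3), 30, 3)
  B <- matrix(rnorm(12 * 3), 12, 3)
  Y <- neural_responses(scale(L, scale = FALSE) %*% t(B), left_index(12))
  fit <- glm_component_fit(L, Y)
  expect_equal(fit$values, B, tolerance = 1e-8, ignore_attr = TRUE)

  # seeded noisy case against the normal-equations oracle
  Yn <- neural_responses(Y$values + matrix(rnorm(30 * 12), 30, 12),
                         left_index(12))
  fitn <- glm_component_fit(L, Yn)
  D <- cbind(1, sweep(L, 2, colMeans(L)))
  oracle <- solve(t(D) %*% D) %*% t(D) %*% Yn$values
  expect_equal(fitn$values, t(oracle[-1, , drop = FALSE]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # with a demeaned design the intercept is the vertex mean response
  expect_equal(fitn$intercepts, colMeans(Yn$values), tolerance = 1e-10,
               ignore_attr = TRUE)

  # collinear design columns are refused
  expect_error(glm_component_fit(cbind(L, L[, 1]), Yn), "collinear")
})

test_that("mirror transport is an involution that preserves values", {
  co <- data.frame(left = 1:10, right = 10:1)
  set.seed(31)
  vals <- rnorm(10)
  right_map <- vertex_map(vals, data.frame(hemisphere = "right", vertex = 1:10))
  mirrored <- mirror_right_to_left(right_map, co)
  expect_equal(sort(mirrored$values), sort(vals))
  expect_identical(mirrored$vertex_index$hemisphere, rep("left", 10))
  # twice returns the original values on the original vertices
  back <- mirror_right_to_left(mirrored, co)
  expect_equal(back$values[order(back$vertex_index$vertex)],
               vals[order(right_map$vertex_index$vertex)])
  # identity correspondence keeps values in place
  ident <- mirror_right_to_left(right_map, data.frame(left = 1:10, right = 1:10))
  expect_equal(ident$values, vals)
  expect_error(mirror_right_to_left(right_map, co[1:5, ]), "unpaired")
})

test_that("symmetry correlations show unit diagonal for mirrored loadings", {
  # construct loadings identical across hemispheres through an identity
  # correspondence, with component 2 = -component 1 to check consistency of
  # the anticorrelation across blocks
  set.seed(32)
  nv <- 30
  base <- matrix(rnorm(nv * 2), nv, 2)
  base[, 2] <- -base[, 1] + 0.05 * rnorm(nv)
  B <- rbind(base, base)
  vi <- rbind(left_index(nv), data.frame(hemisphere = "right", vertex = 1:nv))
  co <- data.frame(left = 1:nv, right = 1:nv)
  null <- permutation_null(rep(0.5, 100))
  thr_l <- threshold_map(vertex_map(rep(1, nv), vi[1:nv, ], "R2"), null)
  thr_r <- threshold_map(vertex_map(rep(1, nv), vi[nv + 1:nv, ], "R2"), null)
  rep_ <- symmetry_correlations(B, vi, thr_l, thr_r, co)
  expect_equal(rep_$roi_size, nv)
  bh <- rep_$correlations[1:2, 3:4]
  expect_equal(diag(bh), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)
  # anticorrelated pair appears anticorrelated between hemispheres too
  expect_lt(abs(bh[1, 2] - rep_$correlations[1, 2]), 0.1)
  expect_lt(bh[1, 2], -0.9)

  # empty ROI is an error
  thr_none <- threshold_map(vertex_map(rep(0, nv), vi[1:nv, ], "R2"), null)
  expect_error(symmetry_correlations(B, vi, thr_none, thr_r, co), "ROI")
})

test_that("symmetric generator yields near-unit between-hemisphere diagonals", {
  cfg <- generator_config(n_concepts = 200, n_stim_dims = 20, k_true = 3,
                          subdivisions = 3, snr = 2, symmetric = TRUE,
                          seed = 33)
  ds <- generate_dataset(cfg)
  s <- standardized_split(ds, 140)
  fit <- fit_plsr(s$Xtr, s$Ytr, 3)
  r2 <- r2_map(s$Yte, predict_responses(fit, s$Xte))
  null <- max_stat_null_r2(s$Xtr, s$Ytr, s$Xte, s$Yte, 3, n_perms = 50,
                           seed = 1)
  maps <- split_map_hemispheres(r2)
  rep_ <- symmetry_correlations(fit$y_loadings, s$Ytr$vertex_index,
                                threshold_map(maps$left, null),
                                threshold_map(maps$right, null),
                                ds$correspondence)
  bh <- diag(rep_$correlations[1:3, 4:6])
  expect_true(all(bh > 0.9))
  # mirrored true right loadings equal the left ones exactly
  nv <- nrow(ds$meshes$left$coordinates)
  A_r <- ds$truth$A_y[nv + 1:nv, 1, drop = TRUE]
  mirrored <- mirror_right_to_left(
    vertex_map(A_r, data.frame(hemisphere = "right", vertex = 1:nv)),
    ds$correspondence)
  expect_identical(mirrored$values[order(mirrored$vertex_index$vertex)],
                   ds$truth$A_y[1:nv, 1])
})

test_that("loading agreement has unit diagonal for identical loadings and flips sign", {
  set.seed(34)
  B <- matrix(rnorm(40 * 3), 40, 3)
  roi <- rep(TRUE, 40)
  same <- loading_agreement(B, B, roi)
  expect_equal(diag(same), rep(1, 3), ignore_attr = TRUE)
  flipped <- B
  flipped[, 2] <- -flipped[, 2]
  expect_equal(diag(loading_agreement(B, flipped, roi))[2], -1,
               ignore_attr = TRUE)
  expect_error(loading_agreement(B, B, rep(FALSE, 40)), "ROI")
})

test_that("Holm adjustment matches the textbook step-down and never adds rejections", {
  # direct check of the worked example through the property table
  set.seed(35)
  out <- property_correlations(matrix(rnorm(200 * 2), 200, 2),
                               concept_matrix(matrix(rnorm(200 * 4), 200, 4)))
  expect_equal(out$p_adj, p.adjust(out$p, "holm"))
  expect_lte(sum(out$p_adj < 0.05), sum(out$p < 0.05))
  # adjusted p never below raw p
  expect_true(all(out$p_adj >= out$p))
  # the canonical worked example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "holm"), c(0.03, 0.04, 0.04))
})

test_that("property correlations are monotone-invariant and recover the assignment", {
  set.seed(36)
  L <- matrix(rnorm(100), 100, 1)
  cubed <- concept_matrix(matrix(L[, 1]^3, 100, 1),
                          feature_labels = "cubed")
  out <- property_correlations(cbind(L, rnorm(100), rnorm(100)), cubed)
  expect_equal(out$rho[out$component == 1], 1)

  # assigned pairs significant, unassigned not, across seeds
  ok <- sapply(1:20, function(s) {
    Z <- with_seed_helper(s, matrix(rnorm(480 * 3), 480, 3))
    ratings <- generate_property_ratings(Z, noise_sd = 0.3, seed = s + 100)
    tab <- property_correlations(Z, ratings)
    a <- attr(ratings, "assignment")
    assigned <- paste(a$latent, a$property)
    tab$pair <- paste(tab$component, tab$property)
    all(tab$significant[tab$pair %in% assigned]) &&
      !any(tab$significant[!tab$pair %in% assigned])
  })
  expect_gte(mean(ok), 0.9)

  expect_error(property_correlations(L, concept_matrix(matrix(1, 100, 1))),
               "constant")
})

test_that("small-sample Spearman p-values agree with exact enumeration", {
  # n = 6: compare the internal exact enumeration with cor.test's exact
  # p-value on tie-free data
  set.seed(37)
  x <- rnorm(6)
  y <- rnorm(6)
  internal <- plsrmap:::.spearman_p(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(internal$rho, unname(ref$estimate))
  expect_equal(internal$p, ref$p.value, tolerance = 1e-12)
})
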