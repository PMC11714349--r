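# Per-vertex prediction accuracy maps and max-statistic permutation
# inference controlling familywise error over the whole surface.

# Vectorized per-column R^2 = 1 - SS_res/SS_tot (SS_tot about the measured
# column means). May be negative. Errors on zero-variance measured columns.
.r2_columns <- function(Ymeas, Ypred) {
  n <- nrow(Ymeas)
  mu <- colMeans(Ymeas)
  ss_tot <- colSums(Ymeas * Ymeas) - n * mu * mu
  if (any(ss_tot <= 0)) {
    stop("measured responses have zero variance at ",
         sum(ss_tot <= 0), " vertex/vertices", call. = FALSE)
  }
  res <- Ymeas - Ypred
  1 - colSums(res * res) / ss_tot
}

#' Per-vertex cross-validated R-squared map
#'
#' For every vertex, the proportion of variance in the measured test
#' responses explained by the predictions: `1 - SS_res / SS_tot`, with
#' `SS_tot` taken about the measured test mean. Values can be negative when
#' predictions do worse than the mean.
#'
#' @param Y_meas measured responses ([neural_responses()]).
#' @param Y_pred predicted responses with identical shape and concept order.
#' @return A [vertex_map()] named `"R2"`.
#' @export
r2_map <- function(Y_meas, Y_pred) {
  Ym <- as_values(Y_meas)
  Yp <- as_values(Y_pred)
  stop_if_not(all(dim(Ym) == dim(Yp)), "shapes must match")
  if (!is.null(rownames(Ym)) && !is.null(rownames(Yp))) {
    stop_if_not(identical(rownames(Ym), rownames(Yp)),
                "concept order must match")
  }
  vi <- if (inherits(Y_meas, "neural_responses")) Y_meas$vertex_index
        else make_vertex_index(rep("left", ncol(Ym)), seq_len(ncol(Ym)))
  vertex_map(.r2_columns(Ym, Yp), vi, name = "R2")
}

#' Elementwise difference of two vertex maps
#'
#' @param map_a,map_b [vertex_map()]s over the same vertex index.
#' @return A [vertex_map()] of `a - b`.
#' @export
r2_difference_map <- function(map_a, map_b) {
  stop_if_not(identical(vertex_keys(map_a$vertex_index),
                        vertex_keys(map_b$vertex_index)),
              "vertex indices must match")
  vertex_map(map_a$values - map_b$values, map_a$vertex_index,
             name = paste0(map_a$name, " - ", map_b$name))
}

#' Permutation null distributions of a map-wide maximum
#'
#' Container for the empirical null of a maximum statistic. The significance
#' threshold is the `ceiling((1 - alpha) * n_perms)`-th smallest maximum
#' (the empirical 95th percentile at `alpha = 0.05`, with no interpolation),
#' so under exchangeability the probability that any vertex exceeds it is at
#' most `alpha`.
#'
#' @param max_stats numeric vector of per-permutation maxima.
#' @param alpha familywise error level.
#' @param seed seed the permutations were drawn with (bookkeeping).
#' @return An object of class `permutation_null`.
#' @export
permutation_null <- function(max_stats, alpha = 0.05, seed = NA_integer_) {
  stop_if_not(length(max_stats) >= 1, "need at least one permutation")
  stop_if_not(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  n <- length(max_stats)
  thr <- sort(max_stats)[ceiling((1 - alpha) * n)]
  structure(list(max_stats = as.numeric(max_stats), n_perms = n,
                 alpha = alpha, seed = seed, threshold = thr),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null: %d permutations, alpha = %g, threshold = %.6g>\n",
              x$n_perms, x$alpha, x$threshold))
  invisible(x)
}

#' Max-statistic permutation null for R-squared maps
#'
#' On each permutation the rows of the training stimulus matrix are shuffled
#' against the fixed training responses, the PLSR is refit at the same `k`,
#' and the unpermuted test set is predicted; the largest R-squared over all
#' vertices is retained. The model is fit to permuted data but tested against
#' unpermuted data, and model-order selection is not re-run inside the loop.
#'
#' @param X_train,Y_train standardized training blocks.
#' @param X_test,Y_test standardized test blocks.
#' @param k number of PLSR components (fixed across permutations).
#' @param n_perms number of permutations (>= 20).
#' @param seed RNG seed; one seeded generator drives all permutations.
#' @param alpha familywise error level.
#' @return A [permutation_null()].
#' @export
max_stat_null_r2 <- function(X_train, Y_train, X_test, Y_test, k,
                             n_perms = 1000L, seed = 1L, alpha = 0.05) {
  stop_if_not(n_perms >= 20, "n_perms must be >= 20")
  Xtr <- as_values(X_train); Ytr <- as_values(Y_train)
  Xte <- as_values(X_test); Yte <- as_values(Y_test)
  stop_if_not(k >= 1 && k <= .mat_rank(Xtr), "invalid component count")
  n <- nrow(Xtr)
  mu <- colMeans(Yte)
  ss_tot <- colSums(Yte * Yte) - nrow(Yte) * mu * mu
  stop_if_not(all(ss_tot > 0), "zero-variance test vertex")
  max_stats <- with_seed(seed, {
    vapply(seq_len(n_perms), function(b) {
      fit <- .fit_plsr_core(Xtr[sample.int(n), , drop = FALSE], Ytr, k)
      Yhat <- Xte %*% fit$x_rotation %*% t(fit$y_loadings)
      res <- Yte - Yhat
      max(1 - colSums(res * res) / ss_tot)
    }, numeric(1))
  })
  permutation_null(max_stats, alpha = alpha, seed = seed)
}

#' Threshold a map against a permutation null
#'
#' Marks vertices whose value strictly exceeds the null threshold (ties at
#' the threshold are not significant).
#'
#' @param map a [vertex_map()].
#' @param null a [permutation_null()].
#' @return An object of class `thresholded_map` with the map, the threshold
#'   and a logical `significant` vector.
#' @export
threshold_map <- function(map, null) {
  stop_if_not(inherits(map, "vertex_map"), "map must be a vertex_map")
  stop_if_not(inherits(null, "permutation_null"),
              "null must be a permutation_null")
  structure(list(map = map, threshold = null$threshold,
                 significant = map$values > null$threshold),
            class = "thresholded_map")
}

#' @export
print.thresholded_map <- function(x, ...) {
  cat(sprintf("<thresholded_map '%s': threshold %.6g, %d / %d vertices significant>\n",
              x$map$name, x$threshold, sum(x$significant),
              length(x$significant)))
  invisible(x)
}
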