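#' Column-wise z-scoring
#'
#' Standardizes every column to mean 0 and standard deviation 1. Training and
#' test sets are standardized independently throughout the pipeline (each set
#' with its own means and sds), matching the procedure the encoding model is
#' defined with.
#'
#' @param x matrix-like object ([concept_matrix()], [neural_responses()] or
#'   plain matrix).
#' @param ddof degrees-of-freedom correction for the standard deviation:
#'   1 (default, sample sd) or 0 (population sd).
#' @return list with `values` (same type as `x`, standardized) and `params`
#'   (list of per-column `means`, `sds`, and `ddof`).
#' @export
zscore_columns <- function(x, ddof = 1L) {
  stop_if_not(ddof %in% c(0L, 1L), "ddof must be 0 or 1")
  m <- as_values(x)
  stop_if_not(nrow(m) > ddof, "too few rows to standardize")
  mu <- colMeans(m)
  sds <- col_sds(m, ddof = ddof)
  if (any(sds == 0)) {
    lab <- colnames(m) %||% as.character(seq_len(ncol(m)))
    stop("constant column(s) cannot be z-scored: ",
         paste(lab[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(m, 2, mu, "-"), 2, sds, "/")
  out <- if (inherits(x, "neural_responses")) {
    neural_responses(z, x$vertex_index, concept_ids = concept_ids(x))
  } else if (inherits(x, "concept_matrix")) {
    dimnames(z) <- dimnames(x)
    concept_matrix(z)
  } else z
  list(values = out,
       params = structure(list(means = mu, sds = sds, ddof = ddof),
                          class = "standardization_params"))
}

# Rank of a matrix via QR with a fixed tolerance.
.mat_rank <- function(m) qr(m)$rank

#' Fit a PLSR encoding model (two-block PLS2, regression mode)
#'
#' Fits partial least squares regression of standardized neural responses `Y`
#' on the standardized stimulus matrix `X` with both-block deflation
#' (regression-mode PLS2). Each component's x-weight vector is the exact
#' fixed point of the NIPALS inner loop — the dominant left singular vector
#' of the cross-covariance `E'F` of the deflated blocks — computed directly
#' by SVD rather than by power iteration, which stalls when residual
#' spectra are nearly degenerate (e.g. fitting more components than the data
#' support). Components are ordered as extracted (first = most predictive of
#' `Y`); the sign of each component is fixed so the largest-magnitude entry
#' of its x-weight vector is positive, making loadings reproducible across
#' runs.
#'
#' The fitted object exposes the stimulus loadings `x_loadings` (reported as
#' B_X; p x k), the neural loadings `y_loadings` (reported as B_Y; vertices x
#' k), the x-weights, the rotation `R_x = W (P'W)^{-1}` such that latent
#' scores are `X R_x`, and the training scores.
#'
#' @param X standardized stimulus matrix (n x p), a [concept_matrix()] or
#'   matrix.
#' @param Y standardized responses (n x v), a [neural_responses()] or matrix.
#' @param k number of components; must not exceed `rank(X)`.
#' @return An object of class `plsr_model`.
#' @export
fit_plsr <- function(X, Y, k) {
  Xm <- as_values(X)
  Ym <- as_values(Y)
  stop_if_not(nrow(Xm) == nrow(Ym), "X and Y must have equal row counts")
  stop_if_not(k >= 1, "k must be >= 1")
  stop_if_not(k <= .mat_rank(Xm), "k exceeds the rank of X")
  fit <- .fit_plsr_core(Xm, Ym, k)
  fit$concept_ids <- rownames(Xm)
  fit$feature_labels <- colnames(Xm)
  if (inherits(Y, "neural_responses")) fit$vertex_index <- Y$vertex_index
  fit
}

# PLS2 regression mode without input validation (hot path for permutation
# loops). Per component, w = dominant left singular vector of E'F (the
# NIPALS fixed point), then t = Ew, p = E't/t't, q = F't/t't and both
# blocks are deflated by t.
.fit_plsr_core <- function(Xm, Ym, k) {
  n <- nrow(Xm); p <- ncol(Xm); v <- ncol(Ym)
  E <- Xm; F_ <- Ym
  W <- matrix(0, p, k); P <- matrix(0, p, k)
  Q <- matrix(0, v, k); Tm <- matrix(0, n, k)
  for (h in seq_len(k)) {
    M <- crossprod(E, F_)
    w <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    if (w[which.max(abs(w))] < 0) w <- -w  # sign convention
    t_ <- E %*% w
    tt <- sum(t_ * t_)
    p_ <- crossprod(E, t_) / tt
    q <- crossprod(F_, t_) / tt
    E <- E - tcrossprod(t_, p_)
    F_ <- F_ - tcrossprod(t_, q)
    W[, h] <- w; P[, h] <- p_; Q[, h] <- q; Tm[, h] <- t_
  }
  Rx <- W %*% solve(crossprod(P, W))
  structure(list(n_components = as.integer(k),
                 x_weights = W, x_loadings = P, y_loadings = Q,
                 x_rotation = Rx, train_scores = Tm),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model: %d components, %d stimulus features, %d vertices>\n",
              x$n_components, nrow(x$x_loadings), nrow(x$y_loadings)))
  invisible(x)
}

#' Project new stimuli into the latent space
#'
#' Computes latent scores `X_new %*% R_x` with the rotation fitted on the
#' training set. Projecting the training stimuli reproduces the training
#' scores.
#'
#' @param model a fitted [fit_plsr()] model.
#' @param X_new standardized stimulus matrix with the same feature columns.
#' @return An object of class `latent_scores` (matrix of scores with a
#'   `source` attribute).
#' @export
project_latent <- function(model, X_new) {
  Xm <- as_values(X_new)
  stop_if_not(ncol(Xm) == nrow(model$x_rotation),
              "X_new must have the model's feature count")
  scores <- Xm %*% model$x_rotation
  colnames(scores) <- sprintf("component_%d", seq_len(model$n_components))
  structure(scores, class = c("latent_scores", class(scores)),
            source = "projected")
}

#' Predict neural responses for new stimuli
#'
#' @param model a fitted [fit_plsr()] model.
#' @param X_new standardized stimulus matrix.
#' @return Predicted responses in standardized units: a [neural_responses()]
#'   if the model carries a vertex index, else a plain matrix.
#' @export
predict_responses <- function(model, X_new) {
  scores <- unclass(project_latent(model, X_new))
  Yhat <- tcrossprod(scores, model$y_loadings)
  rn <- rownames(as_values(X_new))
  if (!is.null(rn)) rownames(Yhat) <- rn
  if (!is.null(model$vertex_index)) {
    neural_responses(Yhat, model$vertex_index,
                     concept_ids = rn %||% as.character(seq_len(nrow(Yhat))))
  } else Yhat
}

#' Cross-validated grid search over component counts
#'
#' Nests an `n_folds`-fold cross-validation inside the training set. Per fold
#' and per candidate `k`, a PLSR is fit to the inner-training part (components
#' are nested in NIPALS, so one fit at `max(k_range)` serves all `k`), the
#' whole-map R-squared on the inner-test part is computed, and its maximum
#' over vertices — the peak whole-brain prediction accuracy — is recorded.
#' Inner training and test parts are z-scored independently.
#'
#' `selected_k` is the smallest `k` whose mean peak R-squared lies within one
#' standard error (sd over folds divided by the square root of the fold
#' count) of the best mean — the classic one-standard-error rule, an
#' automatic stand-in for reading the plateau off the curve.
#'
#' @param X_train,Y_train training stimulus matrix and responses (raw or
#'   standardized; folds are re-standardized internally).
#' @param k_range integer candidate component counts.
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed for the fold assignment.
#' @return An object of class `grid_search_result` with a per-k results
#'   data.frame and `selected_k`.
#' @export
grid_search_components <- function(X_train, Y_train, k_range = 1:10,
                                   n_folds = 5L, seed = 1L) {
  stop_if_not(length(k_range) >= 1, "k_range must be non-empty")
  stop_if_not(n_folds >= 2, "n_folds must be >= 2")
  Xm <- as_values(X_train)
  Ym <- as_values(Y_train)
  n <- nrow(Xm)
  k_range <- sort(unique(as.integer(k_range)))
  kmax <- max(k_range)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  peak <- matrix(NA_real_, n_folds, length(k_range))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    Xtr <- zscore_columns(Xm[tr, , drop = FALSE])$values
    Ytr <- zscore_columns(Ym[tr, , drop = FALSE])$values
    Xte <- zscore_columns(Xm[!tr, , drop = FALSE])$values
    Yte <- zscore_columns(Ym[!tr, , drop = FALSE])$values
    stop_if_not(kmax <= .mat_rank(Xtr), "k exceeds the rank of a fold's X")
    fit <- .fit_plsr_core(Xtr, Ytr, kmax)
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      Rk <- fit$x_weights[, 1:k, drop = FALSE] %*%
        solve(crossprod(fit$x_loadings[, 1:k, drop = FALSE],
                        fit$x_weights[, 1:k, drop = FALSE]))
      Yhat <- Xte %*% Rk %*% t(fit$y_loadings[, 1:k, drop = FALSE])
      peak[f, ki] <- max(.r2_columns(Yte, Yhat))
    }
  }
  means <- colMeans(peak)
  sds <- apply(peak, 2, stats::sd)
  best <- which.max(means)
  se_best <- sds[best] / sqrt(n_folds)
  selected <- k_range[min(which(means >= means[best] - se_best))]
  structure(list(results = data.frame(k = k_range, mean_max_r2 = means,
                                      sd_max_r2 = sds),
                 n_folds = as.integer(n_folds), seed = seed,
                 selected_k = selected, fold_peaks = peak),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result: %d folds, selected_k = %d>\n",
              x$n_folds, x$selected_k))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Full linear-regression encoding baseline
#'
#' Ordinary least squares mapping all stimulus features directly to every
#' vertex response, with no dimensionality reduction and no intercept (inputs
#' are standardized). The comparison model the latent encoding is judged
#' against.
#'
#' @param X_train standardized stimulus matrix (n x p, n > p, full rank).
#' @param Y_train standardized responses (n x v).
#' @return An object of class `linear_baseline` holding the p x v coefficient
#'   matrix; predict with [predict_linear()].
#' @export
fit_linear_baseline <- function(X_train, Y_train) {
  Xm <- as_values(X_train)
  Ym <- as_values(Y_train)
  stop_if_not(nrow(Xm) == nrow(Ym), "X and Y must have equal row counts")
  stop_if_not(nrow(Xm) > ncol(Xm), "need more observations than features")
  dec <- qr(Xm)
  stop_if_not(dec$rank == ncol(Xm), "X is rank-deficient")
  coef <- qr.coef(dec, Ym)
  structure(list(coefficients = coef,
                 vertex_index = if (inherits(Y_train, "neural_responses"))
                   Y_train$vertex_index),
            class = "linear_baseline")
}

#' @rdname fit_linear_baseline
#' @param model a fitted `linear_baseline`.
#' @param X_new standardized stimulus matrix.
#' @export
predict_linear <- function(model, X_new) {
  Xm <- as_values(X_new)
  Yhat <- Xm %*% model$coefficients
  if (!is.null(model$vertex_index)) {
    neural_responses(Yhat, model$vertex_index,
                     concept_ids = rownames(Xm) %||%
                       as.character(seq_len(nrow(Yhat))))
  } else Yhat
}
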