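# Representational similarity analysis: RDM construction (correlation
# distance and per-component absolute difference), RDM-to-RDM correlation on
# lower triangles, and a shared-permutation maximum-statistic threshold over
# layers and components.

.as_rdm <- function(values, metric, ids = NULL) {
  values <- (values + t(values)) / 2   # enforce exact symmetry
  diag(values) <- 0
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  structure(values, class = c("rdm", class(values)), metric = metric)
}

#' Correlation-distance RDM from a feature matrix
#'
#' Entry (i, j) is one minus the Pearson correlation between the feature
#' vectors of concepts i and j (range `[0, 2]`).
#'
#' @param features a [concept_matrix()] (or matrix) with at least 3 feature
#'   columns and no constant rows.
#' @return An `rdm` matrix (symmetric, zero diagonal).
#' @export
correlation_distance_rdm <- function(features) {
  m <- as_values(features)
  stop_if_not(ncol(m) >= 3, "need at least 3 feature columns")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
    stop("constant feature vector for concept(s): ",
         paste(ids[sds == 0], collapse = ", "), call. = FALSE)
  }
  .as_rdm(1 - stats::cor(t(m)), "correlation_distance", rownames(m))
}

#' Correlation-distance RDM of latent scores
#'
#' Correlation distances between concepts' k-dimensional latent score
#' vectors — the full-latent-space RDM.
#'
#' @param L latent scores (concepts x k, k >= 3).
#' @return An `rdm` matrix.
#' @export
latent_rdm <- function(L) {
  Lm <- unclass(as_values(L))
  stop_if_not(ncol(Lm) >= 3, "correlation over latent scores needs k >= 3")
  correlation_distance_rdm(Lm)
}

#' Absolute-difference RDM for a single component
#'
#' Entry (i, j) is the absolute difference in latent scores between concepts
#' i and j along one component.
#'
#' @param scores numeric vector of one component's latent scores.
#' @return An `rdm` matrix.
#' @export
component_absdiff_rdm <- function(scores) {
  s <- as.numeric(scores)
  .as_rdm(abs(outer(s, s, "-")), "absolute_difference", names(scores))
}

#' Correlate two RDMs
#'
#' Pearson (default) or Spearman correlation of the strictly-lower-triangle
#' vectorizations. Both RDMs must index the same concepts in the same order.
#'
#' @param rdm_a,rdm_b RDMs of equal size.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation in `[-1, 1]`.
#' @export
rsa_correlate <- function(rdm_a, rdm_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stop_if_not(all(dim(rdm_a) == dim(rdm_b)), "RDM sizes must match")
  lt <- lower.tri(rdm_a)
  stats::cor(rdm_a[lt], rdm_b[lt], method = method)
}

#' Max-statistic permutation threshold for RSA profiles
#'
#' Correlates every target RDM (full latent space and/or per-component) with
#' every layer RDM, then builds a familywise null: per permutation, one
#' shared reordering of the concepts is applied to the target RDMs (rows and
#' columns), all target-by-layer correlations are recomputed and their
#' maximum retained. The threshold follows the order-statistic rule of
#' [permutation_null()], controlling the familywise error rate over layers
#' (and components, when several targets are supplied).
#'
#' @param target_rdms list of RDMs derived from the latent model.
#' @param layer_rdms list of RDMs derived from layer activations.
#' @param n_perms number of permutations (>= 20).
#' @param seed RNG seed.
#' @param alpha familywise error level.
#' @param method correlation type passed to [rsa_correlate()].
#' @return An object of class `rsa_profile`: `correlations` (targets x
#'   layers), `null` (a [permutation_null()]), `significant` flags.
#' @export
rsa_max_stat_threshold <- function(target_rdms, layer_rdms, n_perms = 10000L,
                                   seed = 1L, alpha = 0.05,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stop_if_not(n_perms >= 20, "n_perms must be >= 20")
  if (inherits(target_rdms, "rdm")) target_rdms <- list(target = target_rdms)
  if (inherits(layer_rdms, "rdm")) layer_rdms <- list(layer = layer_rdms)
  n <- nrow(target_rdms[[1]])
  for (r in c(target_rdms, layer_rdms)) {
    stop_if_not(nrow(r) == n && ncol(r) == n, "all RDMs must have equal size")
  }
  lt <- lower.tri(target_rdms[[1]])
  layer_vecs <- vapply(layer_rdms, function(r) r[lt], numeric(sum(lt)))
  if (method == "spearman") layer_vecs <- apply(layer_vecs, 2, rank)
  obs <- t(vapply(target_rdms, function(tr) {
    v <- tr[lt]
    if (method == "spearman") v <- rank(v)
    as.numeric(stats::cor(v, layer_vecs))
  }, numeric(length(layer_rdms))))
  dimnames(obs) <- list(names(target_rdms) %||%
                          sprintf("target_%d", seq_along(target_rdms)),
                        names(layer_rdms) %||%
                          sprintf("layer_%d", seq_along(layer_rdms)))
  max_stats <- with_seed(seed, {
    vapply(seq_len(n_perms), function(b) {
      sigma <- sample.int(n)
      max(vapply(target_rdms, function(tr) {
        v <- tr[sigma, sigma][lt]
        if (method == "spearman") v <- rank(v)
        max(stats::cor(v, layer_vecs))
      }, numeric(1)))
    }, numeric(1))
  })
  null <- permutation_null(max_stats, alpha = alpha, seed = seed)
  structure(list(correlations = obs, null = null,
                 threshold = null$threshold,
                 significant = obs > null$threshold,
                 method = method),
            class = "rsa_profile")
}

#' @export
print.rsa_profile <- function(x, ...) {
  cat(sprintf("<rsa_profile: %d target(s) x %d layer(s), threshold %.4f (%s)>\n",
              nrow(x$correlations), ncol(x$correlations), x$threshold,
              x$method))
  print(round(x$correlations, 3))
  invisible(x)
}
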