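# Surface-based searchlight decoding: geodesic disc construction along the
# mesh edge graph, predicted-vs-measured pairwise k-NN (k = 1) decoding, and
# its max-statistic permutation null.

#' Build geodesic searchlight discs on a hemisphere mesh
#'
#' For every mask-included vertex, collects the included vertices whose
#' shortest-path distance along the mesh edges (Euclidean edge weights) is at
#' most `radius_mm`. Edge-graph distances slightly overestimate true surface
#' geodesics; discs never leave the hemisphere. A disconnected included
#' region raises a warning and is processed per component.
#'
#' @param mesh a [surface_mesh()].
#' @param mask the hemisphere's [vertex_mask()].
#' @param radius_mm disc radius in mesh units (millimetres).
#' @return An object of class `searchlight_assignment`: `centers` (included
#'   vertex ids), `members` (per center, included vertex ids within radius),
#'   `radius`, `metric`, `hemisphere`.
#' @export
build_searchlights <- function(mesh, mask, radius_mm) {
  stop_if_not(radius_mm >= 0, "radius must be >= 0")
  stop_if_not(length(mask$included) == nrow(mesh$coordinates),
              "mask length must equal the mesh vertex count")
  included <- which(mask$included)
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$coordinates[e[, 1], , drop = FALSE] -
                       mesh$coordinates[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  sub <- igraph::induced_subgraph(g, included)
  if (igraph::components(sub)$no > 1) {
    warning("mask-included region is disconnected; searchlights are built per component")
  }
  d <- igraph::distances(g, v = included, to = included, weights = w)
  lim <- radius_mm * (1 + 1e-9) + 1e-12
  members <- lapply(seq_along(included), function(i) {
    included[d[i, ] <= lim]
  })
  structure(list(centers = included, members = members,
                 radius = radius_mm, metric = "edge_graph_geodesic",
                 hemisphere = mesh$hemisphere),
            class = "searchlight_assignment")
}

#' @export
print.searchlight_assignment <- function(x, ...) {
  sizes <- lengths(x$members)
  cat(sprintf("<searchlight_assignment (%s): %d centers, radius %g, median size %g>\n",
              x$hemisphere, length(x$centers), x$radius, stats::median(sizes)))
  invisible(x)
}

# Map one or more per-hemisphere assignments onto the columns of a
# concatenated neural_responses object. Returns centers as a vertex index
# data.frame plus member column-index lists.
.assignment_columns <- function(assignments, vertex_index) {
  if (inherits(assignments, "searchlight_assignment")) {
    assignments <- list(assignments)
  }
  keys <- vertex_keys(vertex_index)
  centers <- list(); members <- list()
  for (a in assignments) {
    ckeys <- paste(a$hemisphere, a$centers, sep = ":")
    cidx <- match(ckeys, keys)
    stop_if_not(!anyNA(cidx), "searchlight centers missing from the response columns")
    mcols <- lapply(a$members, function(m) {
      idx <- match(paste(a$hemisphere, m, sep = ":"), keys)
      stop_if_not(!anyNA(idx), "searchlight members missing from the response columns")
      idx
    })
    centers[[length(centers) + 1L]] <-
      make_vertex_index(rep(a$hemisphere, length(a$centers)), a$centers)
    members <- c(members, mcols)
  }
  list(centers = do.call(rbind, centers), members = members)
}

#' Predicted-vs-measured pattern correlation matrix
#'
#' Correlates, over a searchlight's member vertices, the predicted response
#' pattern of every concept (rows) with the measured pattern of every concept
#' (columns), yielding the generally asymmetric n x n matrix the pairwise
#' decoding rule operates on.
#'
#' @param Y_pred,Y_meas predicted and measured responses (matching concepts).
#' @param member_vertices column indices of the searchlight's member
#'   vertices (>= 3).
#' @return n x n numeric correlation matrix (rows = predicted,
#'   columns = measured).
#' @export
pattern_correlation_matrix <- function(Y_pred, Y_meas, member_vertices) {
  stop_if_not(length(member_vertices) >= 3,
              "a searchlight needs at least 3 member vertices")
  P <- as_values(Y_pred)[, member_vertices, drop = FALSE]
  M <- as_values(Y_meas)[, member_vertices, drop = FALSE]
  sdP <- apply(P, 1, stats::sd)
  sdM <- apply(M, 1, stats::sd)
  if (any(sdP == 0) || any(sdM == 0)) {
    ids <- rownames(P) %||% as.character(seq_len(nrow(P)))
    bad <- unique(c(ids[sdP == 0], ids[sdM == 0]))
    stop("constant response pattern for concept(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::cor(t(P), t(M))
}

#' Pairwise decoding accuracy from a correlation matrix
#'
#' Two-alternative 1-nearest-neighbor decoding: pair (i, j), i != j, is
#' correct iff the predicted pattern of concept i correlates strictly more
#' with its own measured pattern than with concept j's
#' (`R[i,i] > R[i,j]`; ties count as incorrect). Accuracy is the mean over
#' all off-diagonal pairs.
#'
#' @param R square correlation matrix (rows = predicted, cols = measured).
#' @return Accuracy in `[0, 1]`.
#' @export
pairwise_decoding_accuracy <- function(R) {
  R <- as.matrix(R)
  n <- nrow(R)
  stop_if_not(n == ncol(R) && n >= 2, "R must be square with n >= 2")
  correct <- sum(diag(R) > R) - sum(diag(R) > diag(R))  # strict, excl. diagonal
  correct / (n * (n - 1))
}

#' Whole-surface searchlight decoding map
#'
#' Runs the pairwise decoding statistic in every searchlight and assigns the
#' accuracy to the disc's center vertex. Searchlights with fewer than 3
#' member vertices get no accuracy and are reported in the `"flagged"`
#' attribute.
#'
#' @param Y_pred,Y_meas predicted and measured responses over the same
#'   concepts and vertex index.
#' @param assignment a [build_searchlights()] result or a list of them (one
#'   per hemisphere).
#' @return A [vertex_map()] of accuracies over the center vertices, with
#'   attributes `flagged` (centers with undefined accuracy, their value set
#'   to `NA` removed from the map) and `sizes`.
#' @export
searchlight_decoding_map <- function(Y_pred, Y_meas, assignment) {
  stop_if_not(identical(vertex_keys(Y_pred$vertex_index),
                        vertex_keys(Y_meas$vertex_index)),
              "predicted and measured vertex indices must match")
  ac <- .assignment_columns(assignment, Y_meas$vertex_index)
  sizes <- lengths(ac$members)
  ok <- sizes >= 3
  acc <- rep(NA_real_, length(ac$members))
  for (i in which(ok)) {
    R <- pattern_correlation_matrix(Y_pred, Y_meas, ac$members[[i]])
    acc[i] <- pairwise_decoding_accuracy(R)
  }
  map <- vertex_map(acc[ok], ac$centers[ok, , drop = FALSE],
                    name = "decoding_accuracy")
  attr(map, "flagged") <- ac$centers[!ok, , drop = FALSE]
  attr(map, "sizes") <- sizes[ok]
  map
}

# Per-searchlight strict-less rank matrices: r[i, j] = number of entries in
# row i of R strictly smaller than R[i, j]. After relabeling the measured
# concepts by a permutation sigma, the decoding accuracy equals
# sum_i r[i, sigma(i)] / (n (n - 1)), which lets the permutation null reuse
# the observed correlation matrices.
.decoding_rank_matrices <- function(Y_pred, Y_meas, member_lists) {
  lapply(member_lists, function(cols) {
    R <- pattern_correlation_matrix(Y_pred, Y_meas, cols)
    t(apply(R, 1, function(x) rank(x, ties.method = "min") - 1))
  })
}

#' Max-statistic permutation null for searchlight decoding
#'
#' On each permutation one shared relabeling of the measured concepts is
#' applied to every searchlight (shuffling the columns of each correlation
#' matrix), the whole-surface decoding map is recomputed and its maximum
#' accuracy retained. Sharing the permutation across searchlights preserves
#' the spatial dependence the maximum statistic needs for familywise error
#' control.
#'
#' @inheritParams searchlight_decoding_map
#' @param n_perms number of permutations (>= 20).
#' @param seed RNG seed.
#' @param alpha familywise error level.
#' @return A [permutation_null()].
#' @export
max_stat_null_decoding <- function(Y_pred, Y_meas, assignment,
                                   n_perms = 1000L, seed = 1L, alpha = 0.05) {
  stop_if_not(n_perms >= 20, "n_perms must be >= 20")
  ac <- .assignment_columns(assignment, Y_meas$vertex_index)
  members <- ac$members[lengths(ac$members) >= 3]
  stop_if_not(length(members) > 0, "no searchlight has >= 3 member vertices")
  n <- nrow(as_values(Y_meas))
  ranks <- .decoding_rank_matrices(Y_pred, Y_meas, members)
  big <- do.call(rbind, lapply(ranks, as.vector))  # centers x (n*n), col-major
  denom <- n * (n - 1)
  max_stats <- with_seed(seed, {
    vapply(seq_len(n_perms), function(b) {
      sigma <- sample.int(n)
      idx <- (sigma - 1L) * n + seq_len(n)
      max(rowSums(big[, idx, drop = FALSE])) / denom
    }, numeric(1))
  })
  permutation_null(max_stats, alpha = alpha, seed = seed)
}
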