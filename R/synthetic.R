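#' Configuration for the synthetic surface-data generator
#'
#' Bundles and validates the parameters of [generate_dataset()]. The defaults
#' emulate the study conditions: 720 concepts described by a 66-dimension
#' stimulus embedding, a 5-dimensional shared latent structure, two
#' mirror-symmetric icosphere hemispheres, and a neural signal-to-noise
#' variance ratio of 1 at signal vertices (so the analytic cross-validated
#' R-squared ceiling is snr/(1+snr) = 0.5).
#'
#' @param n_concepts number of object concepts.
#' @param n_stim_dims number of stimulus-embedding dimensions.
#' @param k_true latent dimensionality shared between stimulus and neural
#'   blocks (must not exceed `n_stim_dims`).
#' @param subdivisions icosphere refinement level per hemisphere
#'   (level 3 gives 642 vertices per hemisphere).
#' @param snr ratio of signal variance to noise variance at signal vertices.
#' @param smoothness diffusion (neighbor-averaging) steps applied to the
#'   vertex loading maps.
#' @param symmetric logical; mirror the right hemisphere's loadings and signal
#'   region from the left through the vertex correspondence.
#' @param signal_fraction fraction of vertices per hemisphere carrying signal.
#' @param noise_x_sd standard deviation of additive measurement noise on the
#'   stimulus block. The default 0.02 is small against the per-dimension
#'   signal variance (~k_true/n_stim_dims) and keeps the stimulus matrix
#'   full-rank, as a real behavioral embedding is; set 0 for an exactly
#'   rank-k_true stimulus block.
#' @param mesh_radius hemisphere sphere radius in millimetres.
#' @param seed integer RNG seed; regeneration with an equal config is
#'   bit-identical.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_concepts = 720L, n_stim_dims = 66L,
                             k_true = 5L, subdivisions = 3L, snr = 1,
                             smoothness = 2L, symmetric = TRUE,
                             signal_fraction = 0.25, noise_x_sd = 0.02,
                             mesh_radius = 100, seed = 1L) {
  stop_if_not(k_true >= 1 && k_true <= n_stim_dims,
              "k_true must lie in [1, n_stim_dims]")
  stop_if_not(snr > 0, "snr must be positive")
  stop_if_not(signal_fraction > 0 && signal_fraction <= 1,
              "signal_fraction must lie in (0, 1]")
  stop_if_not(n_concepts >= 4, "n_concepts too small")
  structure(list(n_concepts = as.integer(n_concepts),
                 n_stim_dims = as.integer(n_stim_dims),
                 k_true = as.integer(k_true),
                 subdivisions = as.integer(subdivisions),
                 snr = snr, smoothness = as.integer(smoothness),
                 symmetric = isTRUE(symmetric),
                 signal_fraction = signal_fraction,
                 noise_x_sd = noise_x_sd,
                 mesh_radius = mesh_radius,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Build two mirror-symmetric hemisphere meshes
#'
#' The left hemisphere is an icosphere; the right hemisphere has every x
#' coordinate negated, with triangle orientation flipped so surface normals
#' stay outward. The vertex correspondence between hemispheres is the
#' identity pairing.
#'
#' @param subdivisions icosphere refinement level.
#' @param radius sphere radius (millimetres).
#' @return list with `left`, `right` ([surface_mesh()]) and `correspondence`
#'   (data.frame pairing left and right vertex ids).
#' @export
build_symmetric_hemispheres <- function(subdivisions = 3L, radius = 100) {
  left <- icosphere(subdivisions, radius = radius, hemisphere = "left")
  coords <- left$coordinates
  coords[, 1] <- -coords[, 1]
  right <- surface_mesh(coords, left$triangles[, c(1, 3, 2)],
                        hemisphere = "right")
  nv <- nrow(coords)
  list(left = left, right = right,
       correspondence = data.frame(left = seq_len(nv), right = seq_len(nv)))
}

#' Sample spatially smooth vertex loading maps
#'
#' Draws unit-variance Gaussian noise per vertex and component, then applies
#' `smoothness` rounds of neighbor averaging (graph diffusion) along the mesh
#' edges and rescales every component back to unit variance across vertices.
#' More smoothing steps yield more spatially coherent maps.
#'
#' @param mesh a [surface_mesh()].
#' @param k number of components (columns).
#' @param smoothness number of diffusion steps (0 = raw noise).
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return n_vertices x k numeric matrix with unit-variance columns.
#' @export
sample_smooth_loadings <- function(mesh, k, smoothness = 2L, seed = NULL) {
  stop_if_not(k >= 1, "k must be >= 1")
  with_seed(seed, {
    nv <- nrow(mesh$coordinates)
    A <- matrix(stats::rnorm(nv * k), nv, k)
    if (smoothness > 0) {
      S <- mesh_smoother(mesh)
      for (i in seq_len(smoothness)) A <- as.matrix(S %*% A)
    }
    sweep(A, 2, col_sds(A), "/")
  })
}

# Contiguous signal patch: breadth-first growth from a start vertex until
# `size` vertices are collected.
.grow_patch <- function(mesh, start, size) {
  e <- mesh_edges(mesh)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  seen <- logical(nrow(mesh$coordinates))
  seen[start] <- TRUE
  patch <- start
  frontier <- start
  while (length(patch) < size && length(frontier)) {
    nb <- sort(unique(unlist(adj[as.character(frontier)], use.names = FALSE)))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    take <- min(length(nb), size - length(patch))
    patch <- c(patch, nb[seq_len(take)])
    frontier <- nb
  }
  sort(patch)
}

#' Generate a paired stimulus/neural dataset with known latent truth
#'
#' Draws standard-normal latent scores `Z` (concepts x k_true), orthonormal
#' stimulus loadings `A_x`, and spatially smooth vertex loadings `A_y`
#' (non-zero only on a contiguous signal patch per hemisphere). The observed
#' blocks are `X = Z A_x' + noise` and `Y = Z A_y' + noise`. At every signal
#' vertex the noise draw is centered, orthogonalized against the realized
#' signal and rescaled so the realized signal/noise variance ratio equals
#' `snr` exactly; non-signal vertices carry pure unit-variance noise.
#' Property ratings and depth-graded pseudo-layer activations derived from
#' the same latent scores are included.
#'
#' @param config a [generator_config()].
#' @return A list of class `synthetic_dataset` with elements `X`, `Y`,
#'   `meshes`, `masks`, `correspondence`, `ratings`, `activations`, `truth`
#'   (latent scores, loadings, signal layout, per-vertex noise sd) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stop_if_not(inherits(config, "generator_config"),
              "config must be a generator_config")
  with_seed(config$seed, {
    geom <- build_symmetric_hemispheres(config$subdivisions,
                                        radius = config$mesh_radius)
    nv <- nrow(geom$left$coordinates)
    n <- config$n_concepts
    k <- config$k_true
    p <- config$n_stim_dims

    # latent scores and stimulus loadings
    Z <- matrix(stats::rnorm(n * k), n, k)
    A_x <- qr.Q(qr(matrix(stats::rnorm(p * k), p, k)))
    flip <- apply(A_x, 2, function(col) col[which.max(abs(col))] < 0)
    A_x[, flip] <- -A_x[, flip]
    X <- Z %*% t(A_x)
    if (config$noise_x_sd > 0) {
      X <- X + config$noise_x_sd * matrix(stats::rnorm(n * p), n, p)
    }

    # smooth vertex loadings, mirrored when symmetric
    A_left <- sample_smooth_loadings(geom$left, k, config$smoothness)
    A_right <- if (config$symmetric) {
      A_left[geom$correspondence$right, , drop = FALSE]
    } else {
      sample_smooth_loadings(geom$right, k, config$smoothness)
    }

    # contiguous signal patches
    n_signal <- max(1L, ceiling(config$signal_fraction * nv))
    start_left <- sample.int(nv, 1)
    patch_left <- .grow_patch(geom$left, start_left, n_signal)
    patch_right <- if (config$symmetric) {
      sort(geom$correspondence$right[match(patch_left, geom$correspondence$left)])
    } else {
      .grow_patch(geom$right, sample.int(nv, 1), n_signal)
    }
    signal <- c(seq_len(nv) %in% patch_left, seq_len(nv) %in% patch_right)

    A_y <- rbind(A_left, A_right)
    A_y[!signal, ] <- 0

    # neural block: exact realized SNR at signal vertices
    S <- Z %*% t(A_y)
    V <- 2L * nv
    noise <- matrix(stats::rnorm(n * V), n, V)
    sigma_y <- numeric(V)
    Y <- matrix(0, n, V)
    ctr <- function(v) v - mean(v)
    for (j in seq_len(V)) {
      if (signal[j]) {
        s <- ctr(S[, j])
        e <- ctr(noise[, j])
        e <- e - sum(e * s) / sum(s * s) * s   # decorrelate from signal
        target_sd <- stats::sd(S[, j]) / sqrt(config$snr)
        e <- e * (target_sd / stats::sd(e))
        sigma_y[j] <- target_sd
        Y[, j] <- S[, j] + e
      } else {
        sigma_y[j] <- 1
        Y[, j] <- noise[, j]
      }
    }

    ids <- sprintf("concept_%04d", seq_len(n))
    vi <- make_vertex_index(rep(c("left", "right"), each = nv),
                            rep(seq_len(nv), 2))
    Xcm <- concept_matrix(X, concept_ids = ids,
                          feature_labels = sprintf("dim_%02d", seq_len(p)))
    Ynr <- neural_responses(Y, vi, concept_ids = ids)
    rownames(Z) <- ids

    ratings <- generate_property_ratings(Z, noise_sd = 0.3)
    activations <- generate_layer_activations(Z)

    structure(list(
      X = Xcm, Y = Ynr,
      meshes = list(left = geom$left, right = geom$right),
      masks = list(left = vertex_mask(rep(TRUE, nv), "left"),
                   right = vertex_mask(rep(TRUE, nv), "right")),
      correspondence = geom$correspondence,
      ratings = ratings, activations = activations,
      truth = list(Z = Z, A_x = A_x, A_y = A_y, signal = signal,
                   sigma_y = sigma_y, vertex_index = vi),
      config = config), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d concepts, %d stimulus dims, k_true = %d, %d vertices (%d signal), snr = %g>\n",
    nrow(x$X), ncol(x$X), x$config$k_true, ncol(x$Y$values),
    sum(x$truth$signal), x$config$snr))
  invisible(x)
}

# The 12 object properties reported with the THINGSplus-style metadata.
.property_names <- c("size", "natural", "living", "moving", "manmade",
                     "precious", "heavy", "graspable", "holdable", "movable",
                     "pleasant", "arousing")

#' Generate monotone property ratings from latent scores
#'
#' Each of the 12 properties is a fixed strictly monotone transform of one
#' latent column (cycling through the columns, with alternating sign) plus
#' Gaussian noise. The rating-to-latent assignment is stored in the
#' `"assignment"` attribute so recovery can be checked against ground truth.
#'
#' @param Z latent score matrix (concepts x k).
#' @param noise_sd rating noise standard deviation.
#' @param seed optional seed; `NULL` draws from the current stream.
#' @return A [concept_matrix()] of 12 rating columns with an `assignment`
#'   attribute (data.frame: property, latent, sign, transform).
#' @export
generate_property_ratings <- function(Z, noise_sd = 0.3, seed = NULL) {
  with_seed(seed, {
    n <- nrow(Z)
    k <- ncol(Z)
    transforms <- list(identity = function(x) x,
                       cube = function(x) x^3,
                       signed_sqrt = function(x) sign(x) * sqrt(abs(x)),
                       tanh = function(x) tanh(x))
    m <- length(.property_names)
    latent <- ((seq_len(m) - 1L) %% k) + 1L
    sgn <- rep_len(c(1, -1), m)
    tf <- rep_len(names(transforms), m)
    R <- sapply(seq_len(m), function(j) {
      sgn[j] * transforms[[tf[j]]](Z[, latent[j]]) +
        noise_sd * stats::rnorm(n)
    })
    out <- concept_matrix(R, concept_ids = rownames(Z) %||%
                            as.character(seq_len(n)),
                          feature_labels = .property_names)
    attr(out, "assignment") <- data.frame(property = .property_names,
                                          latent = latent, sign = sgn,
                                          transform = tf,
                                          stringsAsFactors = FALSE)
    out
  })
}

#' Generate depth-graded pseudo-layer activations
#'
#' Emulates network layer activations whose alignment with the latent
#' structure grows with depth: layer l mixes a shared nuisance feature block
#' `N` with a replication of the latent scores, `(1 - w_l) N + w_l [Z ... Z]`,
#' plus feature noise. Replicating `Z` preserves row-wise correlation, so a
#' fully latent-weighted, noise-free layer reproduces the latent RDM exactly.
#'
#' @param Z latent score matrix (concepts x k).
#' @param depth_profile per-layer latent mixing weight in `[0, 1]`, ordered
#'   shallow to deep; default 8 layers ramping 0 to 1.
#' @param replicates number of times `Z` is replicated to form the latent
#'   feature block (features per layer = `replicates * k`).
#' @param noise_sd feature noise standard deviation.
#' @param seed optional seed; `NULL` draws from the current stream.
#' @return Named list of per-layer [concept_matrix()] objects, with the
#'   depth profile stored in the `"depth_profile"` attribute.
#' @export
generate_layer_activations <- function(Z, depth_profile = seq(0, 1, length.out = 8),
                                       replicates = 4L, noise_sd = 0.1,
                                       seed = NULL) {
  stop_if_not(all(depth_profile >= 0 & depth_profile <= 1),
              "depth_profile weights must lie in [0, 1]")
  with_seed(seed, {
    n <- nrow(Z)
    k <- ncol(Z)
    m <- replicates * k
    stop_if_not(m >= 3, "need at least 3 features per layer")
    Zrep <- Z[, rep(seq_len(k), replicates), drop = FALSE]
    N <- matrix(stats::rnorm(n * m), n, m)
    ids <- rownames(Z) %||% as.character(seq_len(n))
    layers <- lapply(seq_along(depth_profile), function(l) {
      w <- depth_profile[l]
      act <- (1 - w) * N + w * Zrep
      if (noise_sd > 0) act <- act + noise_sd * matrix(stats::rnorm(n * m), n, m)
      concept_matrix(act, concept_ids = ids,
                     feature_labels = sprintf("feat_%03d", seq_len(m)))
    })
    names(layers) <- sprintf("layer_%02d", seq_along(depth_profile))
    attr(layers, "depth_profile") <- depth_profile
    layers
  })
}
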