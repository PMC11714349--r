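# Component-level analyses: held-out GLM reproducibility of the neural
# loadings, hemispheric mirror symmetry, PLSR-vs-GLM agreement, and
# latent-score / property-rating correlations.

#' GLM fit of test responses on projected latent scores
#'
#' Demeans each column of the projected latent scores and uses them as a
#' design matrix (plus intercept) in a per-vertex ordinary least squares fit
#' to the measured test responses. The slope coefficients form a matrix the
#' same shape as the PLSR neural loadings (B_Y), estimated from held-out
#' data.
#'
#' @param L_hat_test projected latent scores for the test concepts
#'   (matrix or [project_latent()] output).
#' @param Y_test measured test responses ([neural_responses()] or matrix).
#' @return An object of class `glm_coefficients`: `values` (vertices x k
#'   slopes), `intercepts`, `vertex_index`.
#' @export
glm_component_fit <- function(L_hat_test, Y_test) {
  L <- unclass(as_values(L_hat_test))
  Ym <- as_values(Y_test)
  stop_if_not(nrow(L) == nrow(Ym), "concept counts must match")
  k <- ncol(L)
  stop_if_not(k >= 1, "need at least one component")
  D <- sweep(L, 2, colMeans(L), "-")
  X <- cbind(intercept = 1, D)
  dec <- qr(X)
  stop_if_not(dec$rank == ncol(X), "collinear design columns")
  coef <- qr.coef(dec, Ym)
  structure(list(values = t(coef[-1, , drop = FALSE]),
                 intercepts = coef[1, ],
                 vertex_index = if (inherits(Y_test, "neural_responses"))
                   Y_test$vertex_index,
                 component_labels = colnames(L) %||%
                   sprintf("component_%d", seq_len(k))),
            class = "glm_coefficients")
}

#' @export
print.glm_coefficients <- function(x, ...) {
  cat(sprintf("<glm_coefficients: %d vertices x %d components>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Mirror a right-hemisphere map onto left-hemisphere indexing
#'
#' Transports values through the left-right vertex correspondence (a
#' bijection between the hemispheres' included vertices). Applying the
#' mirror twice returns the original map.
#'
#' @param map_right a [vertex_map()] over right-hemisphere vertices.
#' @param correspondence data.frame with columns `left` and `right` pairing
#'   vertex ids.
#' @return A [vertex_map()] over the paired left-hemisphere vertices.
#' @export
mirror_right_to_left <- function(map_right, correspondence) {
  hemi <- unique(map_right$vertex_index$hemisphere)
  stop_if_not(length(hemi) == 1, "map must cover a single hemisphere")
  to <- if (hemi == "right") "left" else "right"
  from <- hemi
  pos <- match(map_right$vertex_index$vertex, correspondence[[from]])
  if (anyNA(pos)) {
    stop("unpaired included vertex/vertices: ",
         paste(utils::head(map_right$vertex_index$vertex[is.na(pos)], 5),
               collapse = ", "), call. = FALSE)
  }
  vertex_map(map_right$values,
             make_vertex_index(rep(to, length(pos)), correspondence[[to]][pos]),
             name = map_right$name)
}

# Extract a hemisphere's block of a loading matrix keyed by vertex_index,
# restricted to the given vertex ids (in that order).
.loadings_at <- function(values, vertex_index, hemisphere, vertices) {
  keys <- vertex_keys(vertex_index)
  idx <- match(paste(hemisphere, vertices, sep = ":"), keys)
  stop_if_not(!anyNA(idx), "requested vertices missing from the loadings")
  values[idx, , drop = FALSE]
}

#' Hemispheric mirror-symmetry correlations of neural loadings
#'
#' Builds a region of interest from the intersection of the thresholded
#' R-squared maps on the left hemisphere and the mirrored right hemisphere,
#' then correlates all left and mirrored-right component loading maps across
#' the ROI vertices. The 2k x 2k correlation matrix has a left-left block, a
#' right-right block, and a between-hemisphere block whose diagonal measures
#' mirror symmetry of each component.
#'
#' @param B_Y neural loading matrix (vertices x k) over both hemispheres,
#'   e.g. `model$y_loadings`.
#' @param vertex_index the (hemisphere, vertex) index of `B_Y`'s rows.
#' @param r2_left_thresholded,r2_right_thresholded [threshold_map()] results
#'   for each hemisphere's R-squared map.
#' @param correspondence left-right vertex pairing.
#' @return An object of class `symmetry_report`: `correlations` (2k x 2k),
#'   `roi_size`, `roi_vertices`.
#' @export
symmetry_correlations <- function(B_Y, vertex_index, r2_left_thresholded,
                                  r2_right_thresholded, correspondence) {
  k <- ncol(B_Y)
  left_sig <- r2_left_thresholded$map$vertex_index$vertex[
    r2_left_thresholded$significant]
  right_sig <- r2_right_thresholded$map$vertex_index$vertex[
    r2_right_thresholded$significant]
  # mirror right-significant vertices into left indexing
  mirrored <- correspondence$left[match(right_sig, correspondence$right)]
  stop_if_not(!anyNA(mirrored), "unpaired right-hemisphere vertex in ROI")
  roi <- sort(intersect(left_sig, mirrored))
  stop_if_not(length(roi) >= 3, "empty (or too small) intersection ROI")
  left_load <- .loadings_at(B_Y, vertex_index, "left", roi)
  right_ids <- correspondence$right[match(roi, correspondence$left)]
  right_load <- .loadings_at(B_Y, vertex_index, "right", right_ids)
  lab <- c(sprintf("L%d", seq_len(k)), sprintf("R%d", seq_len(k)))
  cc <- stats::cor(cbind(left_load, right_load))
  dimnames(cc) <- list(lab, lab)
  structure(list(correlations = cc, roi_size = length(roi),
                 roi_vertices = roi, n_components = k),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  k <- x$n_components
  bh <- diag(x$correlations[seq_len(k), k + seq_len(k), drop = FALSE])
  cat(sprintf("<symmetry_report: ROI %d vertices, between-hemisphere diagonal %s>\n",
              x$roi_size, paste(sprintf("%.2f", bh), collapse = ", ")))
  invisible(x)
}

#' Agreement between PLSR and GLM neural loadings
#'
#' Pearson correlations, over the vertices of a significance ROI
#' (hemispheres concatenated), between every PLSR neural loading column and
#' every GLM coefficient column.
#'
#' @param B_Y PLSR neural loadings (vertices x k).
#' @param G a [glm_component_fit()] result (or matrix of the same shape).
#' @param roi a [threshold_map()] result defining the ROI (or a logical
#'   vector over the vertices).
#' @return k x k correlation matrix (rows = PLSR, cols = GLM).
#' @export
loading_agreement <- function(B_Y, G, roi) {
  Gm <- if (inherits(G, "glm_coefficients")) G$values else as.matrix(G)
  stop_if_not(all(dim(B_Y) == dim(Gm)), "loading shapes must match")
  sel <- if (inherits(roi, "thresholded_map")) roi$significant else as.logical(roi)
  stop_if_not(length(sel) == nrow(B_Y), "ROI length must match the vertex count")
  stop_if_not(sum(sel) >= 3, "empty (or too small) ROI")
  cc <- stats::cor(B_Y[sel, , drop = FALSE], Gm[sel, , drop = FALSE])
  dimnames(cc) <- list(sprintf("plsr_%d", seq_len(ncol(B_Y))),
                       sprintf("glm_%d", seq_len(ncol(Gm))))
  cc
}

# Two-sided Spearman p-value: exact enumeration up to n = 7, t-approximation
# above.
.spearman_p <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 7) {
    rx <- rank(x); ry <- rank(y)
    perms <- .permutations(n)
    null_rho <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) return(list(rho = rho, p = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Correlate latent scores with object property ratings
#'
#' Spearman correlations (mid-rank ties) between every latent component and
#' every property rating, with Holm step-down adjustment over the full
#' k x n_properties family (or per component).
#'
#' @param L latent scores (concepts x k).
#' @param ratings a [concept_matrix()] of property ratings over the same
#'   concepts.
#' @param alpha significance level for the adjusted flags.
#' @param family `"all"` (default; one Holm family over every pair) or
#'   `"per_component"`.
#' @return A data.frame of class `property_correlation_table` with columns
#'   component, property, rho, p, p_adj, significant.
#' @export
property_correlations <- function(L, ratings, alpha = 0.05,
                                  family = c("all", "per_component")) {
  family <- match.arg(family)
  Lm <- unclass(as_values(L))
  Rm <- as_values(ratings)
  stop_if_not(nrow(Lm) == nrow(Rm), "concept counts must match")
  if (any(col_sds(Rm) == 0)) {
    stop("constant rating column(s): ",
         paste(colnames(Rm)[col_sds(Rm) == 0], collapse = ", "),
         call. = FALSE)
  }
  k <- ncol(Lm)
  props <- colnames(Rm) %||% sprintf("property_%d", seq_len(ncol(Rm)))
  grid <- expand.grid(component = seq_len(k), property = props,
                      stringsAsFactors = FALSE)
  res <- t(mapply(function(ci, pj) {
    sp <- .spearman_p(Lm[, ci], Rm[, pj])
    c(sp$rho, sp$p)
  }, grid$component, match(grid$property, props)))
  out <- data.frame(component = grid$component, property = grid$property,
                    rho = res[, 1], p = res[, 2], stringsAsFactors = FALSE)
  if (family == "all") {
    out$p_adj <- stats::p.adjust(out$p, method = "holm")
  } else {
    out$p_adj <- NA_real_
    for (ci in seq_len(k)) {
      sel <- out$component == ci
      out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "holm")
    }
  }
  out$significant <- out$p_adj < alpha
  attr(out, "alpha") <- alpha
  attr(out, "family") <- family
  class(out) <- c("property_correlation_table", class(out))
  out
}
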