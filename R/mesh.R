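#' Triangle surface meshes
#'
#' Stores vertex coordinates (millimetres) and triangle connectivity for one
#' cortical hemisphere. Triangles are 1-based in memory (GIFTI files store
#' them 0-based; the readers/writers convert). Construction validates that
#' triangle indices are in range, that no triangle has zero area and that the
#' edge graph is connected.
#'
#' @param coordinates numeric n_vertices x 3 matrix.
#' @param triangles integer n_triangles x 3 matrix of 1-based vertex indices.
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(coordinates, triangles, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(coordinates) <- NULL
  dimnames(triangles) <- NULL
  stop_if_not(ncol(coordinates) == 3, "coordinates must be n x 3")
  stop_if_not(ncol(triangles) == 3, "triangles must be n x 3")
  nv <- nrow(coordinates)
  stop_if_not(all(triangles >= 1L) && all(triangles <= nv),
              "triangle index out of range")
  # degenerate (zero-area) triangles
  a <- coordinates[triangles[, 2], , drop = FALSE] - coordinates[triangles[, 1], , drop = FALSE]
  b <- coordinates[triangles[, 3], , drop = FALSE] - coordinates[triangles[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  area2 <- cx * cx + cy * cy + cz * cz
  stop_if_not(all(area2 > 1e-24), "mesh contains degenerate (zero-area) triangles")
  mesh <- structure(list(coordinates = coordinates, triangles = triangles,
                         hemisphere = hemisphere),
                    class = "surface_mesh")
  stop_if_not(.mesh_connected(mesh), "mesh edge graph must be connected")
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh (%s): %d vertices, %d triangles>\n",
              x$hemisphere, nrow(x$coordinates), nrow(x$triangles)))
  invisible(x)
}

# Unique undirected edges (two-column 1-based matrix).
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

.mesh_connected <- function(mesh) {
  nv <- nrow(mesh$coordinates)
  e <- mesh_edges(mesh)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  seen <- logical(nv)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    nb <- unique(unlist(adj[as.character(queue)], use.names = FALSE))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- nb
  }
  all(seen)
}

# Row-stochastic smoothing operator: average of each vertex with its mesh
# neighbors (self included). Sparse, reused across diffusion iterations.
mesh_smoother <- function(mesh) {
  nv <- nrow(mesh$coordinates)
  e <- mesh_edges(mesh)
  i <- c(e[, 1], e[, 2], seq_len(nv))
  j <- c(e[, 2], e[, 1], seq_len(nv))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(A)) %*% A
}

#' Icosphere meshes
#'
#' Builds a geodesic sphere by recursive midpoint subdivision of a regular
#' icosahedron, re-projecting new vertices to the sphere. Subdivision level 0
#' is the icosahedron itself (12 vertices, 20 triangles); each level roughly
#' quadruples the triangle count (level s has `10 * 4^s + 2` vertices).
#'
#' @param subdivisions non-negative integer refinement level.
#' @param radius sphere radius (defaults to 1; use ~100 for a brain-scale
#'   hemisphere in millimetres).
#' @param hemisphere hemisphere tag for the resulting mesh.
#' @return A [surface_mesh()].
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, hemisphere = "left") {
  stop_if_not(subdivisions >= 0, "subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    nv <- nrow(verts)
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      nv <<- nv + 1L
      midpoint_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    r <- 0L
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      newf[r + 1L, ] <- c(a, ab, ca)
      newf[r + 2L, ] <- c(b, bc, ab)
      newf[r + 3L, ] <- c(cc, ca, bc)
      newf[r + 4L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    v <- verts
    f <- newf
  }
  surface_mesh(v * radius, f, hemisphere = hemisphere)
}
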