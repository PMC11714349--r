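#' Concept-by-feature matrices
#'
#' A `concept_matrix` is a numeric matrix with one row per object concept and
#' one column per feature, carrying concept identifiers as row names and
#' feature labels as column names. It is the container for the behavioral
#' stimulus embedding (e.g. 720 concepts by 66 dimensions), property-rating
#' tables and network layer activations.
#'
#' @param values numeric matrix (concepts in rows, features in columns).
#' @param concept_ids character vector of unique concept identifiers; defaults
#'   to the row names of `values`.
#' @param feature_labels character vector of feature labels; defaults to the
#'   column names of `values`.
#' @return A matrix of class `concept_matrix` with dimnames set.
#' @export
concept_matrix <- function(values,
                           concept_ids = rownames(values),
                           feature_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stop_if_not(!anyNA(values) && all(is.finite(values)),
              "concept_matrix values must be finite and non-missing")
  concept_ids <- concept_ids %||% sprintf("concept_%d", seq_len(nrow(values)))
  feature_labels <- feature_labels %||% sprintf("feature_%d", seq_len(ncol(values)))
  stop_if_not(length(concept_ids) == nrow(values),
              "concept_ids must label every row")
  stop_if_not(!anyDuplicated(concept_ids), "concept_ids must be unique")
  stop_if_not(length(feature_labels) == ncol(values),
              "feature_labels must label every column")
  dimnames(values) <- list(as.character(concept_ids), as.character(feature_labels))
  class(values) <- c("concept_matrix", class(values))
  values
}

#' @export
print.concept_matrix <- function(x, ...) {
  cat(sprintf("<concept_matrix: %d concepts x %d features>\n", nrow(x), ncol(x)))
  invisible(x)
}

concept_ids <- function(x) {
  if (inherits(x, "neural_responses")) rownames(x$values) else rownames(x)
}

#' Vertex index tables
#'
#' Columns of a [neural_responses()] matrix are identified by
#' (hemisphere, vertex) pairs so provenance survives hemisphere concatenation.
#' Vertex ids are 1-based mesh indices.
#' @keywords internal
#' @noRd
make_vertex_index <- function(hemisphere, vertex) {
  data.frame(hemisphere = as.character(hemisphere),
             vertex = as.integer(vertex),
             stringsAsFactors = FALSE)
}

vertex_keys <- function(vi) paste(vi$hemisphere, vi$vertex, sep = ":")

#' Concept-by-vertex neural responses
#'
#' Holds a concepts x included-vertices response matrix together with a vertex
#' index recording, per column, the hemisphere and 1-based mesh vertex id.
#' Only mask-included vertices appear: the cortex mask is applied at load or
#' generation time.
#'
#' @param values numeric matrix, concepts in rows, included vertices in columns.
#' @param vertex_index data.frame with columns `hemisphere` and `vertex`, one
#'   row per column of `values`.
#' @param concept_ids unique concept identifiers (defaults to row names).
#' @return An object of class `neural_responses`.
#' @export
neural_responses <- function(values, vertex_index,
                             concept_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stop_if_not(!anyNA(values) && all(is.finite(values)),
              "neural response values must be finite and non-missing")
  stop_if_not(is.data.frame(vertex_index) &&
                all(c("hemisphere", "vertex") %in% names(vertex_index)),
              "vertex_index needs columns 'hemisphere' and 'vertex'")
  stop_if_not(nrow(vertex_index) == ncol(values),
              "vertex_index must have one row per response column")
  stop_if_not(!anyDuplicated(vertex_keys(vertex_index)),
              "vertex_index entries must be unique")
  concept_ids <- concept_ids %||% sprintf("concept_%d", seq_len(nrow(values)))
  stop_if_not(length(concept_ids) == nrow(values),
              "concept_ids must label every row")
  stop_if_not(!anyDuplicated(concept_ids), "concept_ids must be unique")
  rownames(values) <- as.character(concept_ids)
  structure(list(values = values,
                 vertex_index = make_vertex_index(vertex_index$hemisphere,
                                                  vertex_index$vertex)),
            class = "neural_responses")
}

#' @export
print.neural_responses <- function(x, ...) {
  hemis <- table(x$vertex_index$hemisphere)
  cat(sprintf("<neural_responses: %d concepts x %d vertices (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(hemis), hemis), collapse = ", ")))
  invisible(x)
}

#' @export
dim.neural_responses <- function(x) dim(x$values)

#' Per-vertex surface maps
#'
#' A `vertex_map` carries one value per included vertex (an R-squared map, a
#' loading column, a decoding-accuracy map, ...) together with the same
#' (hemisphere, vertex) index used by [neural_responses()].
#'
#' @param values finite numeric vector.
#' @param vertex_index data.frame with `hemisphere` and `vertex` columns.
#' @param name label describing the quantity mapped.
#' @return An object of class `vertex_map`.
#' @export
vertex_map <- function(values, vertex_index, name = "map") {
  values <- as.numeric(values)
  stop_if_not(length(values) == nrow(vertex_index),
              "map length must equal the vertex index length")
  stop_if_not(all(is.finite(values)), "vertex_map values must be finite")
  structure(list(values = values,
                 vertex_index = make_vertex_index(vertex_index$hemisphere,
                                                  vertex_index$vertex),
                 name = name),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf("<vertex_map '%s': %d vertices, range [%.4g, %.4g]>\n",
              x$name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Cortex masks
#'
#' Logical inclusion flag per mesh vertex (TRUE = cortical vertex retained,
#' FALSE = excluded, e.g. the medial wall).
#'
#' @param included logical vector, one entry per mesh vertex.
#' @param hemisphere hemisphere tag of the owning mesh.
#' @return An object of class `vertex_mask`.
#' @export
vertex_mask <- function(included, hemisphere = "left") {
  included <- as.logical(included)
  stop_if_not(!anyNA(included), "mask entries must be TRUE/FALSE")
  stop_if_not(any(included), "a mask must include at least one vertex")
  structure(list(included = included, hemisphere = hemisphere),
            class = "vertex_mask")
}

#' Train/test splits over concepts
#'
#' @param train_indices,test_indices disjoint, non-empty 1-based row index
#'   sets over the concepts.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_indices, test_indices) {
  train_indices <- as.integer(train_indices)
  test_indices <- as.integer(test_indices)
  stop_if_not(length(train_indices) > 0 && length(test_indices) > 0,
              "both split parts must be non-empty")
  stop_if_not(length(intersect(train_indices, test_indices)) == 0,
              "split parts must be disjoint")
  stop_if_not(all(c(train_indices, test_indices) >= 1L),
              "split indices must be positive")
  structure(list(train_indices = train_indices, test_indices = test_indices),
            class = "split_spec")
}

#' First-n / remainder concept split
#'
#' Convenience constructor for the contiguous split used throughout: the first
#' `n_train` concepts train the model, the remainder are held out.
#' @param n_total total number of concepts.
#' @param n_train size of the training part.
#' @export
first_last_split <- function(n_total, n_train) {
  stop_if_not(n_train >= 1 && n_train < n_total,
              "n_train must leave a non-empty test part")
  split_spec(seq_len(n_train), seq.int(n_train + 1L, n_total))
}

#' Split rows of a concept-level object
#'
#' Partitions the rows of a [concept_matrix()] or [neural_responses()] into a
#' training and a test part, preserving row order within each part.
#'
#' @param data object to split.
#' @param spec a [split_spec()].
#' @return list with elements `train` and `test` of the same type as `data`.
#' @export
split_concepts <- function(data, spec) {
  stop_if_not(inherits(spec, "split_spec"), "spec must be a split_spec")
  n <- if (inherits(data, "neural_responses")) nrow(data$values) else nrow(data)
  idx <- c(spec$train_indices, spec$test_indices)
  stop_if_not(max(idx) <= n, "split indices exceed the number of concepts")
  take <- function(i) {
    if (inherits(data, "neural_responses")) {
      neural_responses(data$values[i, , drop = FALSE], data$vertex_index)
    } else {
      concept_matrix(unclass(data)[i, , drop = FALSE])
    }
  }
  list(train = take(spec$train_indices), test = take(spec$test_indices))
}

#' Average rows by group
#'
#' Collapses trial- or image-level rows to one row per group (e.g. averaging
#' the 12 images of every object concept, or averaging subjects). Output rows
#' follow the first-appearance order of the group labels; each output row is
#' the arithmetic mean of its group's rows.
#'
#' @param x a [concept_matrix()] or [neural_responses()].
#' @param group_labels one label per row of `x`.
#' @return Same type as `x`, one row per distinct group label.
#' @export
average_by_group <- function(x, group_labels) UseMethod("average_by_group")

.group_means <- function(values, group_labels) {
  stop_if_not(length(group_labels) == nrow(values),
              "every row needs a group label")
  stop_if_not(length(group_labels) > 0, "no rows / empty group set")
  lev <- unique(as.character(group_labels))
  f <- factor(as.character(group_labels), levels = lev)
  sums <- rowsum(values, f, reorder = FALSE)
  sums / as.vector(table(f))
}

#' @export
average_by_group.concept_matrix <- function(x, group_labels) {
  concept_matrix(.group_means(unclass(x), group_labels))
}

#' @export
average_by_group.neural_responses <- function(x, group_labels) {
  neural_responses(.group_means(x$values, group_labels), x$vertex_index)
}

#' @export
average_by_group.default <- function(x, group_labels) {
  .group_means(as.matrix(x), group_labels)
}

#' Concatenate hemispheres column-wise
#'
#' Binds left- then right-hemisphere responses into one matrix, tagging every
#' column with its hemisphere of origin. Concepts must agree in identity and
#' order. [split_hemispheres()] inverts the operation exactly.
#'
#' @param left,right [neural_responses()] for each hemisphere.
#' @return A [neural_responses()] with left columns followed by right columns.
#' @export
concat_hemispheres <- function(left, right) {
  stop_if_not(inherits(left, "neural_responses") &&
                inherits(right, "neural_responses"),
              "inputs must be neural_responses")
  stop_if_not(identical(concept_ids(left), concept_ids(right)),
              "concept ids must match in identity and order")
  neural_responses(cbind(left$values, right$values),
                   rbind(left$vertex_index, right$vertex_index))
}

#' Split concatenated responses back into hemispheres
#'
#' @param x a [neural_responses()] whose vertex index carries hemisphere tags.
#' @return Named list of per-hemisphere [neural_responses()], in first-seen
#'   hemisphere order.
#' @export
split_hemispheres <- function(x) {
  stop_if_not(inherits(x, "neural_responses"), "x must be neural_responses")
  hemis <- unique(x$vertex_index$hemisphere)
  out <- lapply(hemis, function(h) {
    sel <- x$vertex_index$hemisphere == h
    neural_responses(x$values[, sel, drop = FALSE],
                     x$vertex_index[sel, , drop = FALSE])
  })
  names(out) <- hemis
  out
}
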