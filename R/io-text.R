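# Delimited-text readers/writers. One canonical dialect: tab (or comma)
# separated, '.' decimal, UTF-8, first row = feature labels, first column =
# concept ids. Numbers are written at %.17g so write-then-read is bit-exact.

#' Read a concept-by-feature matrix from delimited text
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A [concept_matrix()].
#' @export
read_concept_matrix <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stop_if_not(file.exists(path), "file not found: ", path)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 2, "expected an id column plus at least one feature")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate concept id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  labels <- colnames(df)[-1]
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(vals) & raw != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at concept '%s', feature '%s'",
                 ids[bad[1, 1]], labels[bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(vals)) {
    stop("missing values are not allowed in a concept matrix", call. = FALSE)
  }
  concept_matrix(vals, concept_ids = ids, feature_labels = labels)
}

#' Write a concept-by-feature matrix to delimited text
#'
#' @param x a [concept_matrix()] (or any labelled numeric matrix).
#' @param path output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param id_header header for the id column.
#' @export
write_concept_matrix <- function(x, path, format = c("tsv", "csv"),
                                 id_header = "concept_id") {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  vals <- as_values(x)
  ids <- rownames(x) %||% as.character(seq_len(nrow(vals)))
  labels <- colnames(x) %||% paste0("f", seq_len(ncol(vals)))
  body <- matrix(fmt_num(vals), nrow(vals), ncol(vals))
  lines <- c(paste(c(id_header, labels), collapse = sep),
             paste(ids, apply(body, 1, paste, collapse = sep), sep = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read/write a cortex mask as one-column TSV
#'
#' The file holds a header line and one 0/1 row per mesh vertex.
#' @param mask a [vertex_mask()].
#' @param path file path.
#' @export
write_vertex_mask <- function(mask, path) {
  writeLines(c("included", as.integer(mask$included)), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vertex_mask
#' @param hemisphere hemisphere tag to attach on read.
#' @export
read_vertex_mask <- function(path, hemisphere = "left") {
  v <- utils::read.table(path, header = TRUE)[[1]]
  stop_if_not(all(v %in% c(0, 1)), "mask file must contain only 0/1")
  vertex_mask(v == 1, hemisphere = hemisphere)
}

# Full-length per-vertex value vector from a one-hemisphere vertex_map:
# excluded vertices are written as zero.
.map_to_full <- function(map, mask) {
  hemi <- unique(map$vertex_index$hemisphere)
  stop_if_not(length(hemi) == 1,
              "write_vertex_map writes one hemisphere at a time")
  n_vertices <- length(mask$included)
  stop_if_not(max(map$vertex_index$vertex) <= n_vertices,
              "map refers to vertices beyond the mesh/mask length")
  stop_if_not(all(mask$included[map$vertex_index$vertex]),
              "map carries values at mask-excluded vertices")
  stop_if_not(sum(mask$included) == length(map$values),
              "map length must equal the number of mask-included vertices")
  full <- numeric(n_vertices)
  full[map$vertex_index$vertex] <- map$values
  full
}

#' Write a per-vertex surface map
#'
#' Writes one hemisphere's map at full precision, with mask-excluded vertices
#' written as zero and the mask saved alongside (`<path>.mask.tsv`). A `.gii`
#' extension selects GIFTI functional format, anything else a one-column TSV.
#'
#' @param map a [vertex_map()] restricted to one hemisphere.
#' @param mask the hemisphere's [vertex_mask()] (defines total vertex count).
#' @param path output path (`*.func.gii` or `*.tsv`).
#' @export
write_vertex_map <- function(map, mask, path) {
  full <- .map_to_full(map, mask)
  if (grepl("\\.gii$", path)) {
    .write_func_gifti(full, path, name = map$name)
  } else {
    writeLines(c(map$name, fmt_num(full)), path, useBytes = TRUE)
  }
  write_vertex_mask(mask, paste0(path, ".mask.tsv"))
  invisible(path)
}

#' Read a per-vertex surface map
#'
#' Inverse of [write_vertex_map()]: reads the full-length vector and restricts
#' it to the mask-included vertices.
#'
#' @param path map file (`*.func.gii` or TSV).
#' @param mask the hemisphere's [vertex_mask()].
#' @param hemisphere hemisphere tag for the resulting map.
#' @return A [vertex_map()].
#' @export
read_vertex_map <- function(path, mask, hemisphere = mask$hemisphere) {
  if (grepl("\\.gii$", path)) {
    res <- .read_func_gifti(path)
    full <- res$values
    name <- res$name
  } else {
    lines <- readLines(path)
    name <- lines[1]
    full <- as.numeric(lines[-1])
  }
  stop_if_not(length(full) == length(mask$included),
              "map length does not match the mask's vertex count")
  idx <- which(mask$included)
  vertex_map(full[idx],
             make_vertex_index(rep(hemisphere, length(idx)), idx),
             name = name)
}
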