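# Minimal GIFTI surface/functional I/O (ASCII encoding), built on xml2.
# Covers exactly what the pipeline needs: POINTSET + TRIANGLE arrays for
# meshes and a single per-vertex data array for functional maps. Triangle
# indices are 0-based on disk (GIFTI convention) and 1-based in memory.

.gifti_data_array <- function(values, intent, datatype, dims) {
  text <- if (datatype == "NIFTI_TYPE_INT32") {
    paste(apply(matrix(as.integer(values), dims[1], dims[2]), 1,
                paste, collapse = " "), collapse = "\n")
  } else {
    paste(apply(matrix(fmt_num(values), dims[1], dims[2]), 1,
                paste, collapse = " "), collapse = "\n")
  }
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
    'Dimensionality="2" Dim0="%d" Dim1="%d" Encoding="ASCII" ',
    'Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
    '<Data>%s</Data>\n</DataArray>'),
    intent, datatype, dims[1], dims[2], text)
}

.gifti_write <- function(arrays, path, metadata = character()) {
  md <- if (length(metadata)) {
    paste0("<MetaData>",
           paste(sprintf("<MD><Name>%s</Name><Value>%s</Value></MD>",
                         names(metadata), metadata), collapse = ""),
           "</MetaData>")
  } else ""
  doc <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">\n',
                        length(arrays)),
                md, "\n", paste(arrays, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

.gifti_read_arrays <- function(path) {
  stop_if_not(file.exists(path), "file not found: ", path)
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//DataArray")
  stop_if_not(length(nodes) > 0, "no DataArray elements in GIFTI file")
  meta <- xml2::xml_find_all(doc, "./MetaData/MD")
  metadata <- stats::setNames(
    xml2::xml_text(xml2::xml_find_first(meta, "./Value")),
    xml2::xml_text(xml2::xml_find_first(meta, "./Name")))
  arrays <- lapply(nodes, function(node) {
    enc <- xml2::xml_attr(node, "Encoding")
    stop_if_not(identical(enc, "ASCII"),
                "only ASCII-encoded GIFTI data arrays are supported (got ",
                enc, ")")
    d0 <- as.integer(xml2::xml_attr(node, "Dim0"))
    d1 <- as.integer(xml2::xml_attr(node, "Dim1") %||% "1")
    if (is.na(d1)) d1 <- 1L
    raw <- scan(text = xml2::xml_text(xml2::xml_find_first(node, "./Data")),
                what = numeric(), quiet = TRUE)
    stop_if_not(length(raw) == d0 * d1, "GIFTI data length mismatch")
    list(intent = xml2::xml_attr(node, "Intent"),
         values = matrix(raw, d0, d1, byrow = TRUE))
  })
  list(arrays = arrays, metadata = metadata)
}

#' Read a GIFTI surface mesh
#'
#' Reads an ASCII-encoded `.surf.gii` file (one POINTSET and one TRIANGLE
#' array). The hemisphere is taken from the `AnatomicalStructurePrimary`
#' metadata when present, else from the argument.
#'
#' @param path path to a `.surf.gii` file.
#' @param hemisphere fallback hemisphere tag.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, hemisphere = "left") {
  g <- .gifti_read_arrays(path)
  intents <- vapply(g$arrays, `[[`, "", "intent")
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  stop_if_not(!is.na(ip) && !is.na(it),
              "surface file needs POINTSET and TRIANGLE arrays")
  anat <- g$metadata[["AnatomicalStructurePrimary"]]
  if (!is.null(anat) && !is.na(anat)) {
    hemisphere <- switch(anat, CortexLeft = "left", CortexRight = "right",
                         hemisphere)
  }
  surface_mesh(g$arrays[[ip]]$values,
               g$arrays[[it]]$values + 1L,
               hemisphere = hemisphere)
}

#' Write a GIFTI surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output path (conventionally `*.surf.gii`).
#' @export
write_mesh <- function(mesh, path) {
  arrays <- c(
    .gifti_data_array(mesh$coordinates, "NIFTI_INTENT_POINTSET",
                      "NIFTI_TYPE_FLOAT64", dim(mesh$coordinates)),
    .gifti_data_array(mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                      "NIFTI_TYPE_INT32", dim(mesh$triangles)))
  anat <- if (mesh$hemisphere == "left") "CortexLeft" else "CortexRight"
  .gifti_write(arrays, path,
               metadata = c(AnatomicalStructurePrimary = anat))
}

.write_func_gifti <- function(full_values, path, name = "map") {
  arr <- .gifti_data_array(full_values, "NIFTI_INTENT_NONE",
                           "NIFTI_TYPE_FLOAT64",
                           c(length(full_values), 1L))
  .gifti_write(arr, path, metadata = c(Name = name))
}

.read_func_gifti <- function(path) {
  g <- .gifti_read_arrays(path)
  stop_if_not(length(g$arrays) == 1, "expected a single functional array")
  nm <- g$metadata[["Name"]]
  list(values = as.numeric(g$arrays[[1]]$values),
       name = if (is.null(nm) || is.na(nm)) "map" else nm)
}
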