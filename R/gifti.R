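## Minimal GIFTI 1.0 XML I/O.
## Reading accepts ASCII, Base64Binary and GZipBase64Binary encodings
## (little-endian); writing uses ASCII so files stay plain text.  Only the
## surface-analysis subset of the standard is covered: POINTSET + TRIANGLE
## geometry, per-vertex scalar/functional arrays, and label arrays.

.giftiTypeInfo <- function(dataType) {
  switch(dataType,
    NIFTI_TYPE_FLOAT32 = list(what = "numeric", size = 4L),
    NIFTI_TYPE_FLOAT64 = list(what = "numeric", size = 8L),
    NIFTI_TYPE_INT32   = list(what = "integer", size = 4L),
    NIFTI_TYPE_UINT8   = list(what = "integer", size = 1L),
    stop("unsupported GIFTI DataType: ", dataType))
}

.decodeDataArray <- function(node) {
  att <- xml2::xml_attrs(node)
  dataType <- att[["DataType"]]
  encoding <- att[["Encoding"]]
  dims <- as.integer(att[sort(grep("^Dim[0-9]$", names(att), value = TRUE))])
  nvals <- prod(dims)
  txt <- xml2::xml_text(xml2::xml_find_first(node, "./Data"))
  vals <- if (encoding == "ASCII") {
    v <- scan(text = txt, what = double(), quiet = TRUE)
    if (.giftiTypeInfo(dataType)$what == "integer") as.integer(v) else v
  } else if (encoding %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (encoding == "GZipBase64Binary")
      raw <- memDecompress(raw, type = "gzip")
    ti <- .giftiTypeInfo(dataType)
    endian <- if (identical(unname(att["Endian"]), "BigEndian")) "big"
              else "little"
    readBin(raw, what = ti$what, n = nvals, size = ti$size, endian = endian,
            signed = ti$size > 1L)
  } else stop("unsupported GIFTI encoding: ", encoding)
  if (length(vals) != nvals)
    stop(sprintf("GIFTI data array has %d values, expected %d",
                 length(vals), nvals))
  order <- if (identical(unname(att["ArrayIndexingOrder"]),
                         "ColumnMajorOrder")) "col" else "row"
  if (length(dims) == 2L) {
    if (order == "row") matrix(vals, dims[1], dims[2], byrow = TRUE)
    else matrix(vals, dims[1], dims[2])
  } else vals
  }

.readGiftiArrays <- function(path) {
  if (!file.exists(path)) stop("GIFTI file not found: ", path)
  doc <- xml2::xml_ns_strip(xml2::read_xml(path))
  nodes <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(nodes, function(nd) {
    list(intent = xml2::xml_attr(nd, "Intent"), data = .decodeDataArray(nd))
  })
}

.giftiHeader <- function() {
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         "<!DOCTYPE GIFTI SYSTEM \"http://www.nitrc.org/frs/download.php/",
         "115/gifti.dtd\">\n")
}

.formatAsciiData <- function(x, integer = FALSE) {
  # row-major serialisation, 8 values per line
  v <- if (is.matrix(x)) as.vector(t(x)) else as.vector(x)
  s <- if (integer) format(as.integer(v), scientific = FALSE, trim = TRUE)
       else formatC(v, digits = 9, format = "g")
  paste(vapply(split(s, ceiling(seq_along(s) / 8)),
               paste, character(1), collapse = " "), collapse = "\n")
}

.dataArrayXml <- function(x, intent, dataType) {
  integer <- dataType %in% c("NIFTI_TYPE_INT32", "NIFTI_TYPE_UINT8")
  dims <- if (is.matrix(x))
    sprintf("Dimensionality=\"2\" Dim0=\"%d\" Dim1=\"%d\"", nrow(x), ncol(x))
  else sprintf("Dimensionality=\"1\" Dim0=\"%d\"", length(x))
  paste0("<DataArray Intent=\"", intent, "\" DataType=\"", dataType, "\" ",
         "ArrayIndexingOrder=\"RowMajorOrder\" ", dims,
         " Encoding=\"ASCII\" Endian=\"LittleEndian\"",
         " ExternalFileName=\"\" ExternalFileOffset=\"\">\n",
         "<MetaData/>\n<Data>", .formatAsciiData(x, integer),
         "</Data>\n</DataArray>\n")
}

.writeGifti <- function(arrays, path, labelTable = NULL) {
  body <- paste(vapply(arrays, function(a)
    .dataArrayXml(a$data, a$intent, a$dataType), character(1)),
    collapse = "")
  lt <- if (is.null(labelTable)) "<LabelTable/>\n" else labelTable
  xml <- paste0(.giftiHeader(),
    "<GIFTI xmlns:xsi=\"http://www.w3.org/2001/XMLSchema-instance\" ",
    "xsi:noNamespaceSchemaLocation=\"http://www.nitrc.org/frs/download.php/",
    "116/gifti.xsd\" Version=\"1.0\" NumberOfDataArrays=\"",
    length(arrays), "\">\n<MetaData/>\n", lt, body, "</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

#' GIFTI surface geometry I/O
#'
#' Reads and writes surface geometry files (\code{.surf.gii}): a POINTSET
#' array of vertex coordinates plus a TRIANGLE array of 0-based vertex
#' indices, converted to the package's 1-based convention on read.
#'
#' @param path file path.
#' @return `readSurfaceGifti()` a [SurfaceMesh-class].
#' @export
readSurfaceGifti <- function(path) {
  arrays <- .readGiftiArrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(ip) || is.na(it))
    stop("not a GIFTI surface file (needs POINTSET and TRIANGLE arrays): ",
         path)
  surfaceMesh(arrays[[ip]]$data, arrays[[it]]$data + 1L)
}

#' @rdname readSurfaceGifti
#' @param mesh a [SurfaceMesh-class].
#' @export
writeSurfaceGifti <- function(mesh, path) {
  validObject(mesh)
  tri <- mesh@triangles - 1L
  storage.mode(tri) <- "integer"
  .writeGifti(list(
    list(data = mesh@vertices, intent = "NIFTI_INTENT_POINTSET",
         dataType = "NIFTI_TYPE_FLOAT32"),
    list(data = tri, intent = "NIFTI_INTENT_TRIANGLE",
         dataType = "NIFTI_TYPE_INT32")), path)
}

#' GIFTI per-vertex scalar / functional data I/O
#'
#' Functional files carry one data array per map; a file with \code{T} maps
#' over \code{n} vertices reads as an \code{n x T} feature matrix.  Writing
#' emits one FLOAT32 array per column.  Round trips preserve values to
#' float32 precision.
#'
#' @param path file path (conventionally \code{.func.gii} / \code{.shape.gii}).
#' @param nExpected optional vertex count to validate against; a mismatch is
#'   an alignment error reporting both counts.
#' @return `readScalarsGifti()` an \code{n x T} numeric matrix.
#' @export
readScalarsGifti <- function(path, nExpected = NULL) {
  arrays <- .readGiftiArrays(path)
  cols <- lapply(arrays, function(a) {
    d <- a$data
    if (is.matrix(d)) d else matrix(d, ncol = 1L)
  })
  out <- do.call(cbind, cols)
  if (!is.null(nExpected) && nrow(out) != nExpected)
    stop(sprintf("alignment error: data file has %d vertices, surface has %d",
                 nrow(out), nExpected))
  out
}

#' @rdname readScalarsGifti
#' @param data numeric vector or \code{n x T} matrix of per-vertex values.
#' @param intent NIFTI intent string for each map.
#' @export
writeScalarsGifti <- function(data, path, intent = "NIFTI_INTENT_NONE") {
  data <- as.matrix(data)
  arrays <- lapply(seq_len(ncol(data)), function(j)
    list(data = data[, j], intent = intent,
         dataType = "NIFTI_TYPE_FLOAT32"))
  .writeGifti(arrays, path)
}

#' GIFTI label (parcellation) I/O
#'
#' Label files map each vertex to an integer key with a label table.  Only
#' the keys are consumed here (cluster ids; 0 = unassigned).
#'
#' @param path file path (conventionally \code{.label.gii}).
#' @return `readLabelsGifti()` an integer vector of per-vertex label keys.
#' @export
readLabelsGifti <- function(path) {
  arrays <- .readGiftiArrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  il <- match("NIFTI_INTENT_LABEL", intents)
  if (is.na(il)) il <- 1L
  as.integer(arrays[[il]]$data)
}

#' @rdname readLabelsGifti
#' @param labels integer vector of per-vertex label keys.
#' @export
writeLabelsGifti <- function(labels, path) {
  labels <- as.integer(labels)
  keys <- sort(unique(labels))
  lt <- paste0("<LabelTable>\n",
    paste(sprintf("<Label Key=\"%d\"><![CDATA[parcel_%d]]></Label>",
                  keys, keys), collapse = "\n"),
    "\n</LabelTable>\n")
  .writeGifti(list(list(data = labels, intent = "NIFTI_INTENT_LABEL",
                        dataType = "NIFTI_TYPE_INT32")), path,
              labelTable = lt)
}
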