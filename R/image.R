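#' Per-pixel HSV feature vectors from an RGB image
#'
#' Treats every pixel as a graph vertex whose "functional data" are the hue,
#' saturation and brightness value of its colour.  Hue is an angle, so it is
#' encoded as a (cos, sin) pair: raw hue would make colours just either side
#' of the red wrap-around (near 0 and near 360 degrees) maximally dissimilar.
#' Channels are scaled to comparable ranges (hue pair in \eqn{[-0.5, 0.5]},
#' saturation and value in \eqn{[0, 1]}).  Pixels are ordered row-major.
#'
#' @param img \code{h x w x 3} RGB array in \eqn{[0, 1]} (as from
#'   [png::readPNG()]), or \code{h x w} grayscale (accepted with a warning;
#'   hue features are then constant).
#' @return \code{(h*w) x 4} feature matrix with attribute \code{"dims"} =
#'   \code{c(h, w)}.
#' @examples
#' f <- imageToFeatures(testImage("two_tone"))
#' attr(f, "dims")
#' @export
imageToFeatures <- function(img) {
  if (length(dim(img)) == 2L) {
    warning("grayscale input: hue features will be constant")
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("expected an h x w x 3 RGB array")
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- rbind(as.vector(t(img[, , 1])),
               as.vector(t(img[, , 2])),
               as.vector(t(img[, , 3])))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  ang <- 2 * pi * hsv[1, ]
  feat <- cbind(cos(ang) / 2, sin(ang) / 2, hsv[2, ], hsv[3, ])
  dimnames(feat) <- NULL
  structure(feat, dims = c(h, w))
}

#' Lattice pixel neighbourhoods
#'
#' Standard 4- or 8-connected pixel adjacency on an \code{h x w} grid,
#' clipped at the borders; the image analogue of the mesh one-ring.
#'
#' @param dims integer vector \code{c(h, w)}, both \code{>= 3}.
#' @param connectivity 4 (rook) or 8 (queen; default, closest in size to the
#'   5-6 vertex mesh one-ring).
#' @return list of neighbour index vectors in row-major pixel order.
#' @export
pixelNeighborhood <- function(dims, connectivity = c(8, 4)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("8", "4"))
  h <- dims[1]; w <- dims[2]
  if (h < 3L || w < 3L) stop("image must be at least 3 x 3")
  offs <- if (connectivity == "4")
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  idx <- function(r, c) (r - 1L) * w + c
  out <- vector("list", h * w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    out[[idx(r, c)]] <- sort(idx(rr[ok], cc[ok]))
  }
  out
}

#' Searchlight VB map of an image
#'
#' Runs the vertex-wise VB searchlight with pixels as vertices: for each
#' pixel, the affinity graph of its own HSV feature vector and those of its
#' lattice neighbours is built and the VB index assigned to the pixel.  The
#' result quantifies image boundaries: values near 0 at sharp transitions,
#' near 1 in homogeneous structure (the grayscale rendering convention is
#' black = 0, white = 1).
#'
#' @param img RGB array (see [imageToFeatures()]), or a feature matrix
#'   carrying a \code{"dims"} attribute.
#' @param connectivity 4 or 8 (default).
#' @param policy an [affinityPolicy()].
#' @param problem eigenproblem, default generalized.
#' @param jobs workers for [parallelMap()].
#' @return \code{h x w} numeric matrix in \eqn{[0, 1]} (\code{NA} where the
#'   neighbourhood has fewer than 3 pixels, which never happens for images
#'   \code{>= 2 x 2} under these connectivities).
#' @examples
#' vb <- imageVbMap(testImage("two_tone", 8))
#' range(vb)
#' @export
imageVbMap <- function(img, connectivity = 8,
                       policy = affinityPolicy(),
                       problem = c("generalized", "standard",
                                   "symmetric_normalized", "random_walk"),
                       jobs = 1L) {
  problem <- match.arg(problem)
  feat <- if (!is.null(attr(img, "dims"))) img else imageToFeatures(img)
  dims <- attr(feat, "dims")
  nb <- pixelNeighborhood(dims, connectivity)
  vb <- parallelMap(seq_len(nrow(feat)), function(p) {
    hood <- c(p, nb[[p]])
    if (length(hood) < 3L) return(NA_real_)
    w <- tryCatch(
      buildAffinity(feat[hood, , drop = FALSE], policy, degenerate = "zero"),
      error = function(e) NULL)
    if (is.null(w)) return(NA_real_)
    suppressWarnings(vbIndex(w, problem, isolated = "drop"))
  }, jobs = jobs)
  matrix(vapply(vb, identity, numeric(1)), dims[1], dims[2], byrow = TRUE)
}

#' Write a VB map as a grayscale PNG
#'
#' @param vbMap \code{h x w} matrix in \eqn{[0, 1]}; \code{NA} is rendered
#'   as 0.
#' @param path output path.
#' @export
writeVbPng <- function(vbMap, path) {
  m <- replace(vbMap, is.na(vbMap), 0)
  m[m < 0] <- 0
  m[m > 1] <- 1
  png::writePNG(m, path)
  invisible(path)
}
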