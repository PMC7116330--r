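#' One-ring adjacency of a surface mesh
#'
#' Vertex \code{j} is a one-ring neighbour of \code{i} iff some triangle
#' contains both.  This is the "directly adjacent vertices" neighbourhood
#' used by the searchlight; on a regular cortical mesh it has 5 or 6 members.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return list of length \code{nVertices(mesh)}; element \code{i} is the
#'   sorted integer vector of neighbours of vertex \code{i} (empty for
#'   orphan vertices).
#' @examples
#' ring <- oneRing(makeIcosphere(0))
#' lengths(ring)    # every icosahedron vertex has 5 neighbours
#' @export
oneRing <- function(mesh) {
  validObject(mesh)
  tr <- mesh@triangles
  n <- nrow(mesh@vertices)
  # each triangle contributes its three undirected edges, both directions
  from <- c(tr[, 1], tr[, 2], tr[, 2], tr[, 3], tr[, 3], tr[, 1])
  to   <- c(tr[, 2], tr[, 1], tr[, 3], tr[, 2], tr[, 1], tr[, 3])
  adj <- split(to, factor(from, levels = seq_len(n)))
  unname(lapply(adj, function(v) sort(unique(v))))
}

#' k-ring neighbourhood by breadth-first expansion
#'
#' Non-canonical extension of the one-ring searchlight: vertices within
#' \code{k} edge hops.  The canonical searchlight neighbourhood is strictly
#' the one-ring (\code{k = 1}).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param k ring depth, \code{k >= 1}.
#' @return list of neighbour index vectors (centre excluded), as [oneRing()].
#' @export
kRing <- function(mesh, k = 1L) {
  if (k < 1L) stop("k must be >= 1")
  ring <- oneRing(mesh)
  if (k == 1L) return(ring)
  lapply(seq_along(ring), function(v) {
    seen <- v
    frontier <- ring[[v]]
    for (step in seq_len(k)) {
      frontier <- setdiff(frontier, seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
      frontier <- unique(unlist(ring[frontier], use.names = FALSE))
    }
    sort(setdiff(seen, v))
  })
}

# regular icosahedron with unit circumradius
.icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(1 + p^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  surfaceMesh(v, f)
}

#' Generate an icosphere mesh
#'
#' Starts from a regular icosahedron and applies \code{subdivisions} rounds
#' of 4-to-1 midpoint subdivision, projecting every vertex to the unit
#' sphere.  Vertex count is \eqn{10 \cdot 4^s + 2}; all vertices have 6
#' one-ring neighbours except the 12 original ones, which have 5 -- the same
#' local structure as the standard spherical cortical meshes.  Used as the
#' closed-surface fixture for synthetic experiments.
#'
#' @param subdivisions integer in \code{[0, 6]}.
#' @return a [SurfaceMesh-class] on the unit sphere.
#' @examples
#' nVertices(makeIcosphere(2))   # 162
#' @export
makeIcosphere <- function(subdivisions = 0L) {
  if (length(subdivisions) != 1L || is.na(subdivisions) ||
      subdivisions < 0 || subdivisions > 6)
    stop("subdivisions must be an integer in [0, 6]")
  mesh <- .icosahedron()
  for (s in seq_len(subdivisions)) {
    v <- mesh@vertices
    f <- mesh@triangles
    n <- nrow(v)
    # unique undirected edges, midpoint id lookup by edge key
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- t(apply(e, 1L, sort))
    key <- paste(e[, 1], e[, 2])
    uk <- !duplicated(key)
    mid <- match(key, key[uk]) + n
    mv <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2
    mv <- mv / sqrt(rowSums(mv^2))
    m <- nrow(f)
    ab <- mid[seq_len(m)]
    bc <- mid[m + seq_len(m)]
    ca <- mid[2 * m + seq_len(m)]
    newf <- rbind(
      cbind(f[, 1], ab, ca),
      cbind(f[, 2], bc, ab),
      cbind(f[, 3], ca, bc),
      cbind(ab, bc, ca))
    mesh <- surfaceMesh(rbind(v, mv), newf)
  }
  mesh
}

#' Write / read a mesh as CSV (fallback exchange format)
#'
#' Two plain CSV files: \code{<prefix>_vertices.csv} (x,y,z per row) and
#' \code{<prefix>_triangles.csv} (three 1-based indices per row).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param prefix path prefix for the two files.
#' @return `readSurfaceCsv()` a [SurfaceMesh-class]; `writeSurfaceCsv()` the
#'   prefix, invisibly.
#' @export
writeSurfaceCsv <- function(mesh, prefix) {
  utils::write.table(mesh@vertices, paste0(prefix, "_vertices.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(mesh@triangles, paste0(prefix, "_triangles.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname writeSurfaceCsv
#' @export
readSurfaceCsv <- function(prefix) {
  v <- as.matrix(utils::read.csv(paste0(prefix, "_vertices.csv"),
                                 header = FALSE))
  f <- as.matrix(utils::read.csv(paste0(prefix, "_triangles.csv"),
                                 header = FALSE))
  dimnames(v) <- dimnames(f) <- NULL
  surfaceMesh(v, f)
}
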