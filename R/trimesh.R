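#' Triangle mesh objects
#'
#' A `trimesh` stores vertex coordinates in meters and a triangle index
#' list. It is the central geometric object: all trait extraction, clipping
#' and capture simulation operate on it.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in meters.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

edge_table <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

#' Count boundary (open) edges of a mesh
#'
#' An edge is open when it is not shared by exactly two faces. Watertight,
#' consistently oriented meshes have zero open edges and every directed
#' edge appears exactly once.
#'
#' @param mesh a [trimesh].
#' @return integer count of defective undirected edges.
#' @export
open_edge_count <- function(mesh) {
  e <- edge_table(mesh)
  base <- nrow(mesh$vertices) + 1
  key <- sort(pmin(e[, 1], e[, 2]) * base + pmax(e[, 1], e[, 2]))
  runs <- rle(key)
  sum(runs$lengths != 2L)
}

#' Test whether a mesh is watertight and consistently oriented
#'
#' @param mesh a [trimesh].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  e <- edge_table(mesh)
  base <- nrow(mesh$vertices) + 1
  if (anyDuplicated(e[, 1] * base + e[, 2]) > 0) return(FALSE)
  open_edge_count(mesh) == 0L
}

#' Enclosed volume of a watertight mesh
#'
#' Signed divergence-theorem sum of tetrahedron volumes spanned by each
#' triangle and the origin. Translation- and rotation-invariant, additive
#' over disjoint closed components. Refuses meshes that are not watertight.
#'
#' @param mesh a watertight, consistently oriented [trimesh].
#' @return volume in cubic meters (positive).
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh)) {
    stop(sprintf(
      "mesh is not watertight (%d defective edges); volume is undefined",
      open_edge_count(mesh)))
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # a . (b x c) / 6 per triangle
  vol <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
             a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
             a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  abs(vol)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas; degenerate triangles contribute zero.
#'
#' @param mesh a [trimesh].
#' @return area in square meters.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Apply a rigid (or scaled rigid) transform to a mesh
#'
#' @param mesh a [trimesh].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (meters).
#' @param scale scalar scale factor applied before rotation.
#' @return transformed [trimesh].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- (mesh$vertices * scale) %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  trimesh(v, mesh$faces)
}

#' Drop degenerate faces (repeated vertex indices)
#' @param mesh a [trimesh].
#' @return cleaned [trimesh].
#' @keywords internal
drop_degenerate_faces <- function(mesh) {
  f <- mesh$faces
  bad <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(bad)) mesh$faces <- f[!bad, , drop = FALSE]
  mesh
}

#' Rotation matrix about a coordinate axis
#' @param axis one of "x", "y", "z".
#' @param angle angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3),
    y = matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3),
    z = matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3))
}
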