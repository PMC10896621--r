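#' Analytic solid meshes
#'
#' Reference solids (cube, icosphere, ellipsoid, capped cylinder) with
#' closed-form volume/area, used to validate the mesh operators and the
#' capture chain against analytic ground truth.
#'
#' @param side cube edge length in meters.
#' @return a watertight [trimesh].
#' @export
cube_mesh <- function(side = 1) {
  v <- matrix(c(
    0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
    0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1), ncol = 3, byrow = TRUE) * side
  f <- matrix(c(
    1, 3, 2,  1, 4, 3,   # bottom
    5, 6, 7,  5, 7, 8,   # top
    1, 2, 6,  1, 6, 5,   # y = 0
    3, 4, 8,  3, 8, 7,   # y = 1
    1, 5, 8,  1, 8, 4,   # x = 0
    2, 3, 7,  2, 7, 6),  # x = 1
    ncol = 3, byrow = TRUE)
  trimesh(v, f)
}

#' @rdname cube_mesh
#' @param radius sphere radius in meters.
#' @param subdivisions icosahedron subdivision level (4 gives ~5k faces).
#' @param center sphere center.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1, phi, 0,   1, phi, 0,   -1, -phi, 0,  1, -phi, 0,
    0, -1, phi,   0, 1, phi,   0, -1, -phi,  0, 1, -phi,
    phi, 0, -1,   phi, 0, 1,   -phi, 0, -1,  -phi, 0, 1),
    ncol = 3, byrow = TRUE)
  f <- matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
    ncol = 3, byrow = TRUE)
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    new_v <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      new_v[[length(new_v) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      id <- nv + length(new_v)
      assign(key, id, envir = mid_cache)
      id
    }
    nf <- nrow(f)
    f2 <- matrix(0L, nf * 4L, 3L)
    for (t in seq_len(nf)) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      f2[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, new_v))
    f <- f2
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  trimesh(v, f)
}

#' @rdname cube_mesh
#' @param semi_axes length-3 vector of ellipsoid half-axes (meters).
#' @export
ellipsoid_mesh <- function(semi_axes = c(1, 1, 1), subdivisions = 3,
                           center = c(0, 0, 0)) {
  m <- icosphere(1, subdivisions)
  v <- sweep(m$vertices, 2, semi_axes, "*")
  v <- sweep(v, 2, center, "+")
  trimesh(v, m$faces)
}

#' @rdname cube_mesh
#' @param length_x cylinder length along the x axis (meters).
#' @param n_segments number of angular segments.
#' @export
cylinder_mesh <- function(radius = 0.5, length_x = 2, n_segments = 96,
                          center = c(0, 0, 0)) {
  theta <- seq(0, 2 * pi, length.out = n_segments + 1)[-(n_segments + 1)]
  x0 <- -length_x / 2; x1 <- length_x / 2
  ring0 <- cbind(x0, radius * cos(theta), radius * sin(theta))
  ring1 <- cbind(x1, radius * cos(theta), radius * sin(theta))
  v <- rbind(ring0, ring1, c(x0, 0, 0), c(x1, 0, 0))
  c0 <- 2L * n_segments + 1L
  c1 <- 2L * n_segments + 2L
  i <- seq_len(n_segments)
  j <- c(i[-1], 1L)
  side <- rbind(cbind(i, j, n_segments + j), cbind(i, n_segments + j, n_segments + i))
  cap0 <- cbind(c0, j, i)                                  # normal -x
  cap1 <- cbind(c1, n_segments + i, n_segments + j)        # normal +x
  m <- trimesh(sweep(v, 2, center, "+"), rbind(side, cap0, cap1))
  m
}

#' Perimeter of an ellipse by adaptive quadrature
#'
#' Arc length of the ellipse with half-axes `a`, `b`, used as an independent
#' oracle for girth measurements on elliptic cross-sections.
#'
#' @param a,b half-axes in meters.
#' @return perimeter in meters.
#' @export
ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}
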