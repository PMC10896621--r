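#' Extract the zero iso-surface of a scalar field on a regular grid
#'
#' Evaluates `field_fn` (negative inside, positive outside) at the nodes of
#' a regular grid covering `lower`..`upper` (padded by two voxels) and
#' triangulates the zero level set with marching tetrahedra. The result is
#' watertight provided the surface does not touch the padded grid boundary.
#'
#' @param field_fn function taking an n x 3 matrix of points, returning n
#'   signed values (negative inside).
#' @param lower,upper length-3 numeric, bounding box of the solid (meters).
#' @param spacing grid spacing in meters.
#' @return a [trimesh].
#' @export
extract_isosurface <- function(field_fn, lower, upper, spacing) {
  stopifnot(length(lower) == 3, length(upper) == 3, spacing > 0)
  lower <- lower - 2 * spacing
  upper <- upper + 2 * spacing
  xs <- seq(lower[1], upper[1] + spacing, by = spacing)
  ys <- seq(lower[2], upper[2] + spacing, by = spacing)
  zs <- seq(lower[3], upper[3] + spacing, by = spacing)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                KEEP.OUT.ATTRS = FALSE))
  f <- field_fn(grid)
  if (length(f) != nrow(grid)) stop("field_fn returned wrong length")
  res <- .mtet_extract(as.numeric(f),
                       c(length(xs), length(ys), length(zs)),
                       c(lower[1], lower[2], lower[3]), spacing)
  drop_degenerate_faces(trimesh(res$vertices, res$faces))
}

# Polynomial smooth minimum of two pseudo-distance fields; blend radius k.
smooth_min <- function(a, b, k = 0.03) {
  h <- pmax(k - abs(a - b), 0) / k
  pmin(a, b) - h * h * k * 0.25
}

# Signed pseudo-distance to a capsule (segment p0-p1 with radius r).
capsule_field <- function(p, p0, p1, r) {
  d <- p1 - p0
  len2 <- sum(d^2)
  w <- sweep(p, 2, p0, "-")
  t <- pmin(pmax((w %*% d) / len2, 0), 1)
  dx <- w[, 1] - t * d[1]
  dy <- w[, 2] - t * d[2]
  dz <- w[, 3] - t * d[3]
  sqrt(dx^2 + dy^2 + dz^2) - r
}

# Pseudo-distance to an axis-aligned ellipsoid (scaled radial distance).
ellipsoid_field <- function(p, center, half_axes, scale = min(half_axes)) {
  u <- sweep(p, 2, center, "-")
  r <- sqrt((u[, 1] / half_axes[1])^2 + (u[, 2] / half_axes[2])^2 +
            (u[, 3] / half_axes[3])^2)
  (r - 1) * scale
}
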