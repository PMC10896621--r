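#' Pinhole depth camera model
#'
#' Intrinsics in pixels, pose mapping the camera frame to the world frame
#' (OpenCV convention: x right, y down, z along the optical axis). Depth is
#' projective: the z coordinate of the surface point in the camera frame.
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels.
#' @param width,height image size in pixels.
#' @param rotation 3 x 3 rotation, camera axes as columns (camera-to-world).
#' @param translation camera origin in world coordinates, meters.
#' @param min_depth,max_depth valid depth range, meters.
#' @param quant_step depth discretisation step in meters (0 = continuous).
#' @param noise_sd additive Gaussian depth noise SD in meters.
#' @return a `camera_model` object.
#' @export
camera_model <- function(fx, fy = fx, cx = width / 2, cy = height / 2,
                         width = 848, height = 480,
                         rotation = diag(3), translation = c(0, 0, 0),
                         min_depth = 0.2, max_depth = 5,
                         quant_step = 0, noise_sd = 0) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (quant_step < 0) stop("quantization step must be non-negative")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-8 || abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 rotation = rotation, translation = as.numeric(translation),
                 min_depth = min_depth, max_depth = max_depth,
                 quant_step = quant_step, noise_sd = noise_sd),
            class = "camera_model")
}

#' Camera looking at a target point
#'
#' @param position camera origin in world coordinates.
#' @param target world point on the optical axis.
#' @param up world up direction (used to fix the roll).
#' @param ... further arguments to [camera_model()].
#' @return a `camera_model`.
#' @export
look_at_camera <- function(position, target, up = c(0, 0, 1), ...) {
  z <- target - position
  z <- z / sqrt(sum(z^2))
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("optical axis parallel to the up direction")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  camera_model(rotation = unname(cbind(x, y, z)), translation = position,
               ...)
}

#' Default 15-camera acquisition rig
#'
#' Five cameras on each side and five overhead, surrounding a subject
#' standing near the origin with its longitudinal axis along x. The side
#' tiers mix floor-level cameras (seeing the belly and the inner faces of
#' the opposite legs under the torso), high flank cameras and a low frontal
#' camera for the head and jaw; the overhead row includes end-on views onto
#' the rump (behind) and the face/chest (ahead), so that every surface
#' point of the default adult preset except the ground-contact hoof soles
#' is seen by at least one camera. Geometry is a declared assumption of
#' the simulator, fully configurable.
#'
#' @param width,height image size in pixels.
#' @param fx focal length in pixels (scaled with `width` so the field of
#'   view is resolution-independent).
#' @param quant_step depth discretisation step in meters.
#' @param noise_sd depth noise SD in meters.
#' @return a `rig_config`: list of 15 [camera_model()]s; the common frame
#'   is by convention the upper-middle camera's (index
#'   `reference_camera`), with all poses known in the simulator.
#' @export
default_rig <- function(width = 848, height = round(width * 480 / 848),
                        fx = width * 660 / 848, quant_step = 0.002,
                        noise_sd = 0) {
  side_spec <- list(
    list(pos = c(-1.30, 1.55, 0.06), tgt = c(-0.45, 0.25, 0.58)),
    list(pos = c(-0.95, 1.70, 1.20), tgt = c(-0.80, 0.00, 0.95)),
    list(pos = c(0.90, 1.55, 0.06), tgt = c(0.10, 0.25, 0.60)),
    list(pos = c(0.30, 1.70, 1.30), tgt = c(0.30, 0.00, 0.85)),
    list(pos = c(1.90, 1.45, 0.55), tgt = c(1.30, 0.00, 1.00)))
  top_spec <- list(
    list(pos = c(-1.75, 0, 1.75), tgt = c(-0.82, 0, 0.90)),
    list(pos = c(-0.75, 0, 2.55), tgt = c(-0.50, 0, 0.90)),
    list(pos = c(0.20, 0, 2.55), tgt = c(0.20, 0, 0.90)),
    list(pos = c(1.10, 0, 2.55), tgt = c(0.95, 0, 0.90)),
    list(pos = c(2.15, 0, 2.05), tgt = c(1.45, 0, 1.05)))
  cams <- list()
  for (sgn in c(1, -1)) {
    for (s in side_spec) {
      cams[[length(cams) + 1L]] <- look_at_camera(
        s$pos * c(1, sgn, 1), s$tgt * c(1, sgn, 1), width = width,
        height = height, fx = fx, quant_step = quant_step,
        noise_sd = noise_sd)
    }
  }
  for (s in top_spec) {
    cams[[length(cams) + 1L]] <- look_at_camera(
      s$pos, s$tgt, up = c(1, 0, 0), width = width, height = height,
      fx = fx, quant_step = quant_step, noise_sd = noise_sd)
  }
  structure(list(cameras = cams, reference_camera = 13L),
            class = "rig_config")
}

#' @export
print.rig_config <- function(x, ...) {
  cat(sprintf("rig_config: %d cameras, reference camera #%d\n",
              length(x$cameras), x$reference_camera))
  invisible(x)
}

#' Depth map object
#'
#' A grid of projective depths in meters with `NA` marking invalid pixels,
#' together with the camera that produced it.
#'
#' @param depth numeric matrix (height x width), meters, `NA` = invalid.
#' @param cam the [camera_model()].
#' @return a `depth_map` object.
#' @export
depth_map <- function(depth, cam) {
  structure(list(depth = depth, cam = cam), class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  v <- x$depth[is.finite(x$depth)]
  cat(sprintf("depth_map: %d x %d px, %d valid (%.1f%%), depth %.3f-%.3f m\n",
              ncol(x$depth), nrow(x$depth), length(v),
              100 * length(v) / length(x$depth),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Render the depth map of a mesh as seen by a camera
#'
#' Ray casts the mesh through every pixel; a valid pixel carries the
#' projective depth (camera-frame z) of the first intersection, clamped to
#' the camera's depth range. Pixels missing the mesh are invalid. Additive
#' Gaussian noise is applied when the camera's `noise_sd` is positive
#' (uses the current RNG state). A camera inside the mesh yields an
#' all-invalid map with a warning.
#'
#' @param mesh a [trimesh].
#' @param cam a [camera_model()].
#' @return a `depth_map`.
#' @export
render_depth <- function(mesh, cam) {
  vc <- sweep(mesh$vertices, 2, cam$translation, "-") %*% cam$rotation
  # containment by ray parity, probed in two generic directions (avoids
  # miscounts from rays through vertices, and open meshes never test inside)
  probe <- c(0.1234567, 0.2345678, 0.9654321)
  inside <- .ray_hit_count(vc, mesh$faces, c(0, 0, 0), probe) %% 2L == 1L &&
    .ray_hit_count(vc, mesh$faces, c(0, 0, 0), -probe) %% 2L == 1L
  if (inside) {
    warning("camera origin lies inside the mesh; all pixels invalid")
    return(depth_map(matrix(NA_real_, cam$height, cam$width), cam))
  }
  d <- .raycast_depth(vc, mesh$faces, cam$fx, cam$fy, cam$cx, cam$cy,
                      cam$width, cam$height)
  d[!is.na(d) & (d < cam$min_depth | d > cam$max_depth)] <- NA_real_
  if (cam$noise_sd > 0) {
    ok <- !is.na(d)
    d[ok] <- d[ok] + stats::rnorm(sum(ok), 0, cam$noise_sd)
  }
  depth_map(d, cam)
}

#' Quantize a depth map
#'
#' Rounds valid depths to the nearest multiple of `step` (the staircase
#' discretisation of a stereo depth sensor); `step = 0` is the identity.
#'
#' @param d a `depth_map`.
#' @param step quantization step in meters.
#' @return a `depth_map`.
#' @export
quantize_depth <- function(d, step = d$cam$quant_step) {
  if (step < 0) stop("step must be non-negative")
  if (step == 0) return(d)
  d$depth <- round(d$depth / step) * step
  d
}

#' Edge-preserving smoothing of a depth map
#'
#' Joint spatial/range (bilateral) filter: reduces the quantization
#' staircase on smooth regions while leaving the validity mask untouched
#' and not blurring across depth discontinuities much larger than
#' `range_sigma`.
#'
#' @param d a `depth_map`.
#' @param spatial_radius window radius in pixels (>= 1).
#' @param range_sigma range kernel SD in meters; pick a few quantization
#'   steps so staircase levels are averaged but object boundaries are not.
#' @return a `depth_map`.
#' @export
smooth_depth <- function(d, spatial_radius = 4, range_sigma = 0.006) {
  if (spatial_radius < 1) stop("spatial_radius must be >= 1")
  d$depth <- .bilateral_depth(d$depth, as.integer(spatial_radius),
                              spatial_radius / 2, range_sigma)
  d
}

#' Oriented point cloud
#'
#' @param points n x 3 matrix of world coordinates (m).
#' @param normals n x 3 matrix of unit normals, camera-facing.
#' @param camera integer source-camera index per point.
#' @return a `point_cloud` object.
#' @export
point_cloud <- function(points, normals, camera = rep(1L, nrow(points))) {
  points <- as.matrix(points)
  normals <- as.matrix(normals)
  if (!all(dim(points) == dim(normals))) stop("points/normals mismatch")
  nn <- sqrt(rowSums(normals^2))
  if (any(abs(nn - 1) > 1e-6)) normals <- normals / nn
  structure(list(points = points, normals = normals,
                 camera = as.integer(camera)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d oriented points from %d camera(s)\n",
              nrow(x$points), length(unique(x$camera))))
  invisible(x)
}

#' Back-project a depth map into an oriented point cloud
#'
#' One world-frame point per valid pixel; normals are estimated from the
#' local depth gradient and oriented toward the source camera.
#'
#' @param d a `depth_map`.
#' @param cam the camera (defaults to the one stored in the map).
#' @param camera_index source index stored with the points.
#' @return a `point_cloud` in the world frame.
#' @export
backproject <- function(d, cam = d$cam, camera_index = 1L) {
  z <- d$depth
  h <- nrow(z); w <- ncol(z)
  u <- matrix(rep(0:(w - 1), each = h), h, w)
  v <- matrix(rep(0:(h - 1), w), h, w)
  X <- (u + 0.5 - cam$cx) / cam$fx * z
  Y <- (v + 0.5 - cam$cy) / cam$fy * z

  shift <- function(m, di, dj) {
    out <- matrix(NA_real_, h, w)
    si <- max(1, 1 - di):min(h, h - di)
    sj <- max(1, 1 - dj):min(w, w - dj)
    out[si, sj] <- m[si + di, sj + dj]
    out
  }
  diffc <- function(m, di, dj) {
    fwd <- shift(m, di, dj) - m
    bwd <- m - shift(m, -di, -dj)
    ctr <- (shift(m, di, dj) - shift(m, -di, -dj)) / 2
    out <- ctr
    out[is.na(out)] <- fwd[is.na(out)]
    out[is.na(out)] <- bwd[is.na(out)]
    out
  }
  dXu <- diffc(X, 0, 1); dYu <- diffc(Y, 0, 1); dZu <- diffc(z, 0, 1)
  dXv <- diffc(X, 1, 0); dYv <- diffc(Y, 1, 0); dZv <- diffc(z, 1, 0)
  nxm <- dYu * dZv - dZu * dYv
  nym <- dZu * dXv - dXu * dZv
  nzm <- dXu * dYv - dYu * dXv

  ok <- is.finite(z)
  pts <- cbind(X[ok], Y[ok], z[ok])
  nrm <- cbind(nxm[ok], nym[ok], nzm[ok])
  ln <- sqrt(rowSums(nrm^2))
  bad <- !is.finite(ln) | ln < 1e-12
  nrm[bad, ] <- matrix(rep(c(0, 0, -1), sum(bad)), ncol = 3, byrow = TRUE)
  ln[bad] <- 1
  nrm <- nrm / ln
  # orient toward the camera (origin of the camera frame)
  flip <- rowSums(nrm * pts) > 0
  nrm[flip, ] <- -nrm[flip, ]
  pw <- sweep(pts %*% t(cam$rotation), 2, cam$translation, "+")
  nw <- nrm %*% t(cam$rotation)
  point_cloud(pw, nw, rep(as.integer(camera_index), nrow(pw)))
}

#' Rigid pose estimation from corresponding 3D points
#'
#' Least-squares rigid transform (Kabsch/Umeyama without scale) mapping
#' points observed in camera B's frame onto the same points observed in
#' camera A's frame: `a ~ R b + t`. This is the checkerboard extrinsic
#' calibration step between consecutive camera pairs.
#'
#' @param board_points_cam_a,board_points_cam_b n x 3 matrices of
#'   corresponding checkerboard corner coordinates (n >= 3, not collinear).
#' @return list with `rotation` (3 x 3) and `translation` (length 3).
#' @export
calibrate_pair <- function(board_points_cam_a, board_points_cam_b) {
  A <- as.matrix(board_points_cam_a)
  B <- as.matrix(board_points_cam_b)
  if (nrow(A) != nrow(B)) stop("corner count mismatch")
  if (nrow(A) < 3) stop("at least 3 corresponding corners required")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(crossprod(Bc, Ac))  # H = Bc^T Ac
  if (sv$d[2] < max(sv$d[1], 1e-300) * 1e-9)
    stop(sprintf(paste0("degenerate (collinear) corner configuration: ",
                        "singular values %.3g / %.3g / %.3g"),
                 sv$d[1], sv$d[2], sv$d[3]))
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t <- ca - as.numeric(R %*% cb)
  list(rotation = R, translation = t)
}

#' Compose and invert rigid poses
#' @param p1,p2 poses as `list(rotation, translation)`; the composition
#'   applies `p2` first, then `p1`.
#' @return a pose list.
#' @export
compose_pose <- function(p1, p2) {
  list(rotation = p1$rotation %*% p2$rotation,
       translation = as.numeric(p1$rotation %*% p2$translation) +
         p1$translation)
}

#' @rdname compose_pose
#' @param p a pose.
#' @export
invert_pose <- function(p) {
  list(rotation = t(p$rotation),
       translation = as.numeric(-t(p$rotation) %*% p$translation))
}

#' Identity pose
#' @export
identity_pose <- function() list(rotation = diag(3), translation = c(0, 0, 0))

#' Merge oriented point clouds into a common frame
#'
#' Applies each cloud's pose (mapping it into the common frame, by
#' convention the upper reference camera's frame or the world frame) and
#' concatenates, with optional voxel de-duplication.
#'
#' @param clouds list of `point_cloud`s.
#' @param poses list of poses (`list(rotation, translation)`), one per
#'   cloud.
#' @param dedup_radius voxel radius in meters for de-duplication
#'   (0 disables; default 5 mm).
#' @return a merged `point_cloud`.
#' @export
merge_clouds <- function(clouds, poses = NULL, dedup_radius = 0.005) {
  if (is.null(poses)) poses <- replicate(length(clouds),
                                         identity_pose(), simplify = FALSE)
  if (length(clouds) != length(poses)) stop("pose count mismatch")
  pts <- list(); nrm <- list(); cam <- list()
  for (i in seq_along(clouds)) {
    cl <- clouds[[i]]
    R <- poses[[i]]$rotation
    tt <- poses[[i]]$translation
    pts[[i]] <- sweep(cl$points %*% t(R), 2, tt, "+")
    nrm[[i]] <- cl$normals %*% t(R)
    cam[[i]] <- cl$camera
  }
  p <- do.call(rbind, pts)
  n <- do.call(rbind, nrm)
  cm <- unlist(cam)
  if (dedup_radius > 0) {
    key <- paste(round(p[, 1] / dedup_radius),
                 round(p[, 2] / dedup_radius),
                 round(p[, 3] / dedup_radius))
    keep <- !duplicated(key)
    p <- p[keep, , drop = FALSE]
    n <- n[keep, , drop = FALSE]
    cm <- cm[keep]
  }
  point_cloud(p, n, cm)
}

reconstruction_error <- function(msg, ...) {
  stop(structure(class = c("reconstruction_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Reconstruct a watertight surface from an oriented point cloud
#'
#' Builds a signed scalar field on a regular grid (inverse-distance
#' weighted signed distance to the tangent planes of the k nearest cloud
#' points) and extracts its zero level set with marching tetrahedra — an
#' implicit point-set-surface reconstruction. Insufficient coverage (a
#' cloud that does not close a surface) is reported as a structured
#' `reconstruction_error`, never returned as a silently wrong mesh.
#'
#' @param cloud an oriented `point_cloud` covering a closed surface.
#' @param voxel grid spacing in meters.
#' @param k number of nearest neighbours blended per grid node.
#' @param coverage_max_dist maximum tolerated distance from reconstructed
#'   surface patches to the nearest cloud point (98th percentile over face
#'   centroids); larger values indicate hallucinated surface in uncovered
#'   regions.
#' @return a watertight [trimesh].
#' @export
reconstruct_surface <- function(cloud, voxel = 0.01, k = 8,
                                coverage_max_dist = max(6 * voxel, 0.04)) {
  p <- cloud$points
  if (nrow(p) < 100)
    reconstruction_error("too few points (%d) for surface reconstruction",
                         nrow(p))
  lower <- apply(p, 2, min) - 4 * voxel
  upper <- apply(p, 2, max) + 4 * voxel
  xs <- seq(lower[1], upper[1] + voxel, by = voxel)
  ys <- seq(lower[2], upper[2] + voxel, by = voxel)
  zs <- seq(lower[3], upper[3] + voxel, by = voxel)
  nd <- c(length(xs), length(ys), length(zs))
  field <- .cloud_signed_field(p, cloud$normals, nd, lower, voxel,
                               as.integer(k))
  # force the outermost layer outside so the level set always closes;
  # uncovered regions that get capped this way are caught by the coverage
  # check below
  dim(field) <- nd
  field[c(1, nd[1]), , ] <- abs(field[c(1, nd[1]), , ]) + voxel
  field[, c(1, nd[2]), ] <- abs(field[, c(1, nd[2]), ]) + voxel
  field[, , c(1, nd[3])] <- abs(field[, , c(1, nd[3])]) + voxel
  res <- .mtet_extract(as.numeric(field), nd, lower, voxel)
  mesh <- drop_degenerate_faces(trimesh(res$vertices, res$faces))
  if (nrow(mesh$faces) == 0)
    reconstruction_error("empty reconstruction (no zero level set)")
  if (!is_watertight(mesh))
    reconstruction_error("non-watertight reconstruction (%d open edges)",
                         open_edge_count(mesh))
  cent <- (mesh$vertices[mesh$faces[, 1], ] +
           mesh$vertices[mesh$faces[, 2], ] +
           mesh$vertices[mesh$faces[, 3], ]) / 3
  dmax <- stats::quantile(.nearest_point_distance(p, cent), 0.98)
  if (dmax > coverage_max_dist)
    reconstruction_error(
      "insufficient cloud coverage: 98%% of surface within %.3f m of data, tolerance %.3f m",
      dmax, coverage_max_dist)
  mesh
}

#' Simulate the full one-shot acquisition of a mesh with a rig
#'
#' Renders a depth map per camera, applies quantization and bilateral
#' smoothing, back-projects, merges all clouds (camera poses are known by
#' construction in the simulator) and reconstructs the surface.
#'
#' @param mesh the source [trimesh].
#' @param rig a `rig_config`.
#' @param smooth logical; apply [smooth_depth()].
#' @param spatial_radius,range_sigma smoothing parameters.
#' @param dedup_radius merge de-duplication radius (m).
#' @param voxel reconstruction grid spacing (m).
#' @return list with `cloud` (merged `point_cloud`) and `mesh`
#'   (reconstructed [trimesh]).
#' @export
simulate_capture <- function(mesh, rig, smooth = TRUE, spatial_radius = 4,
                             range_sigma = 0.006, dedup_radius = 0.005,
                             voxel = 0.01) {
  clouds <- list()
  for (i in seq_along(rig$cameras)) {
    cam <- rig$cameras[[i]]
    d <- render_depth(mesh, cam)
    if (all(is.na(d$depth))) next
    d <- quantize_depth(d)
    if (smooth) d <- smooth_depth(d, spatial_radius, range_sigma)
    clouds[[length(clouds) + 1L]] <- backproject(d, camera_index = i)
  }
  if (length(clouds) == 0)
    reconstruction_error("no camera produced a valid depth map")
  merged <- merge_clouds(clouds, dedup_radius = dedup_radius)
  list(cloud = merged, mesh = reconstruct_surface(merged, voxel = voxel))
}
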