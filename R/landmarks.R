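#' Anatomical feature points
#'
#' Named landmark coordinates plus longitudinal cutting stations. Landmarks
#' are the machine-readable stand-in for the interactive point clicking a
#' human operator performs on the reconstructed mesh. Stations are stored
#' as pseudo-landmarks (3D anchor points); the cutting plane at a station
#' is orthogonal to the body's longitudinal axis and passes through the
#' anchor. Trait measurement derives the body frame (longitudinal, lateral,
#' vertical axes) from the landmarks themselves, which makes all traits
#' invariant under rigid motion of mesh and landmarks together.
#'
#' @param landmarks numeric matrix with rownames among `withers`,
#'   `hip_left`, `hip_right`, `pin_left`, `pin_right`, `shoulder_tip_left`,
#'   `shoulder_tip_right`, `buttock_tip_left`, `buttock_tip_right`;
#'   columns x, y, z in meters.
#' @param stations either a named numeric vector of x coordinates or a
#'   named 4 x 3 matrix of anchor points, with names `rump_plane`,
#'   `abdomen_station`, `chest_station`, `shoulder_plane`, strictly
#'   increasing along the longitudinal axis in that order.
#' @param mesh optional [trimesh]; when given, landmarks are checked to lie
#'   within 1 cm of its surface.
#' @return an object of class `feature_points`.
#' @export
feature_points <- function(landmarks, stations, mesh = NULL) {
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 3) stop("landmarks must have 3 columns")
  if (is.null(rownames(landmarks))) stop("landmarks must be named (rownames)")
  dimnames(landmarks) <- list(rownames(landmarks), NULL)
  need <- c("rump_plane", "abdomen_station", "chest_station", "shoulder_plane")
  if (is.matrix(stations)) {
    if (!all(need %in% rownames(stations)))
      stop("stations must contain: ", paste(need, collapse = ", "))
    st <- stations[need, , drop = FALSE]
    dimnames(st) <- list(need, NULL)
  } else {
    if (!all(need %in% names(stations)))
      stop("stations must contain: ", paste(need, collapse = ", "))
    st <- cbind(stations[need], 0, 0)
    rownames(st) <- need
  }
  fp <- structure(list(landmarks = landmarks, stations = st),
                  class = "feature_points")
  ax <- tryCatch(body_frame(fp)$x, error = function(e) c(1, 0, 0))
  s_along <- as.numeric(st %*% ax)
  if (any(diff(s_along) <= 0))
    stop("stations must be strictly ordered ",
         "rump_plane < abdomen_station < chest_station < shoulder_plane")
  if (!is.null(mesh)) {
    d <- .point_mesh_distance(mesh$vertices, mesh$faces, landmarks)
    if (any(d > 0.01))
      warning(sprintf("%d landmark(s) farther than 1 cm from the mesh surface",
                      sum(d > 0.01)))
  }
  fp
}

#' @export
print.feature_points <- function(x, ...) {
  cat(sprintf("feature_points: %d landmarks (%s), 4 stations\n",
              nrow(x$landmarks),
              paste(rownames(x$landmarks), collapse = ", ")))
  invisible(x)
}

#' Body frame derived from landmarks
#'
#' Lateral axis from the hip landmarks, longitudinal axis from buttock tips
#' toward shoulder tips (orthogonalised), vertical axis as their cross
#' product. Returns unit axes `x` (longitudinal, toward the head),
#' `y` (lateral, toward the left) and `z` (up).
#'
#' @param fp a [feature_points] object.
#' @return list of three unit vectors.
#' @export
body_frame <- function(fp) {
  lm <- fp$landmarks
  pick <- function(n) {
    if (!n %in% rownames(lm)) stop("missing landmark: ", n)
    lm[n, ]
  }
  y_raw <- if (all(c("hip_left", "hip_right") %in% rownames(lm)))
    pick("hip_left") - pick("hip_right")
  else pick("pin_left") - pick("pin_right")
  front <- (pick("shoulder_tip_left") + pick("shoulder_tip_right")) / 2
  rear <- if (all(c("buttock_tip_left", "buttock_tip_right") %in% rownames(lm)))
    (pick("buttock_tip_left") + pick("buttock_tip_right")) / 2
  else (pick("pin_left") + pick("pin_right")) / 2
  x_raw <- front - rear
  yhat <- y_raw / sqrt(sum(y_raw^2))
  x_perp <- x_raw - sum(x_raw * yhat) * yhat
  xhat <- x_perp / sqrt(sum(x_perp^2))
  zhat <- c(xhat[2] * yhat[3] - xhat[3] * yhat[2],
            xhat[3] * yhat[1] - xhat[1] * yhat[3],
            xhat[1] * yhat[2] - xhat[2] * yhat[1])
  list(x = xhat, y = yhat, z = zhat)
}

# extreme point of the contour obtained by slicing the mesh with a plane
# orthogonal to coordinate `slice_axis` at `at`; interpolated contours make
# the landmarks insensitive to the mesh resolution.
section_extreme <- function(mesh, at, coord, which = c("max", "min"),
                            slice_axis = 1, torso_only = TRUE,
                            subset_fn = NULL) {
  perm <- c(slice_axis, setdiff(1:3, slice_axis))
  m2 <- trimesh(mesh$vertices[, perm, drop = FALSE], mesh$faces)
  sec <- cross_section(m2, at)
  pts <- if (torso_only) sec$loops[[sec$torso]] else do.call(rbind, sec$loops)
  inv <- order(perm)
  pts <- pts[, inv, drop = FALSE]
  if (!is.null(subset_fn)) {
    keep <- subset_fn(pts)
    if (!any(keep)) stop("no contour points satisfy the landmark constraint")
    pts <- pts[keep, , drop = FALSE]
  }
  which <- match.arg(which)
  i <- if (which == "max") which.max(pts[, coord]) else which.min(pts[, coord])
  pts[i, ]
}

#' Exact landmarks of a synthetic cow mesh
#'
#' Places the nine landmarks deterministically from interpolated section
#' contours of the mesh: withers at the dorsal-most point of the shoulder
#' section, hips/pins as the lateral extremes of sections near the rump and
#' the tail, shoulder tips as the lateral extremes at the shoulder plane
#' and buttock tips as the rearmost contour points at pin height. These are
#' the noise-free "true clicks" that study generation jitters.
#'
#' @param mesh a cow [trimesh] from [make_cow_mesh()].
#' @param params the [cow_params()] that generated the mesh.
#' @return a [feature_points] object.
#' @export
cow_landmarks <- function(mesh, params) {
  x_sh <- station_x(params, params$shoulder_plane_frac)
  x_hip <- station_x(params, max(params$rump_plane_frac + 0.05, 0.17))
  x_pin <- station_x(params, 0.06)
  withers <- section_extreme(mesh, x_sh, 3, "max")
  hip_l <- section_extreme(mesh, x_hip, 2, "max")
  hip_r <- section_extreme(mesh, x_hip, 2, "min")
  pin_l <- section_extreme(mesh, x_pin, 2, "max")
  pin_r <- section_extreme(mesh, x_pin, 2, "min")
  sh_l <- section_extreme(mesh, x_sh, 2, "max")
  sh_r <- section_extreme(mesh, x_sh, 2, "min")
  # buttock tips: rearmost contour points at pin height on each side
  z_pin <- (pin_l[3] + pin_r[3]) / 2
  off <- 0.15 * params$torso_half_height  # clear of the tail
  bt_l <- section_extreme(mesh, z_pin, 1, "min", slice_axis = 3,
                          torso_only = FALSE,
                          subset_fn = function(p) p[, 2] > off)
  bt_r <- section_extreme(mesh, z_pin, 1, "min", slice_axis = 3,
                          torso_only = FALSE,
                          subset_fn = function(p) p[, 2] < -off)
  lm <- rbind(withers = withers, hip_left = hip_l, hip_right = hip_r,
              pin_left = pin_l, pin_right = pin_r,
              shoulder_tip_left = sh_l, shoulder_tip_right = sh_r,
              buttock_tip_left = bt_l, buttock_tip_right = bt_r)
  zc <- torso_center_z(params)
  st_x <- c(rump_plane = station_x(params, params$rump_plane_frac),
            abdomen_station = station_x(params, params$abdomen_station_frac),
            chest_station = station_x(params, params$chest_station_frac),
            shoulder_plane = x_sh)
  stations <- cbind(st_x, 0, zc)
  rownames(stations) <- names(st_x)
  feature_points(lm, stations)
}

#' Apply a rigid transform to feature points
#' @param fp a [feature_points] object.
#' @inheritParams transform_mesh
#' @return transformed [feature_points].
#' @export
transform_feature_points <- function(fp, rotation = diag(3),
                                     translation = c(0, 0, 0), scale = 1) {
  lm <- sweep((fp$landmarks * scale) %*% t(rotation), 2, translation, "+")
  st <- sweep((fp$stations * scale) %*% t(rotation), 2, translation, "+")
  rownames(st) <- rownames(fp$stations)
  feature_points(lm, st)
}

#' Mirror feature points across the median (y = 0) plane
#'
#' Swaps left/right landmark names so the mirrored set describes the
#' mirrored animal.
#'
#' @param fp a [feature_points] object.
#' @return mirrored [feature_points].
#' @export
mirror_feature_points <- function(fp) {
  lm <- fp$landmarks
  lm[, 2] <- -lm[, 2]
  rn <- rownames(lm)
  rn2 <- sub("_left$", "_TMP", rn)
  rn2 <- sub("_right$", "_left", rn2)
  rn2 <- sub("_TMP$", "_right", rn2)
  rownames(lm) <- rn2
  st <- fp$stations
  st[, 2] <- -st[, 2]
  feature_points(lm, st)
}
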