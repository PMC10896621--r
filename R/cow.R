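#' Parametric cow body model
#'
#' `cow_params()` assembles the parameter set of the synthetic animal: a
#' lofted superellipsoid torso, four capped-cylinder legs, an optional
#' neck/head capsule and a withers bump, smoothly unioned into one implicit
#' solid. The default preset is calibrated to adult Holstein scale (total
#' volume roughly 0.6-0.8 m^3, withers height roughly 1.4-1.5 m).
#'
#' The longitudinal axis is x with the head toward +x, z is vertical with
#' the ground plane at z = 0. Cutting stations are given as fractions of
#' torso length, 0 at the tail end and 1 at the shoulder end.
#'
#' @param torso_half_length,torso_half_width,torso_half_height torso
#'   half-axes in meters.
#' @param torso_shape_exponents length-2 dimensionless pair
#'   (cross-section, profile); `c(1, 1)` gives a pure ellipsoid.
#' @param leg_length,leg_radius leg geometry in meters; the torso centre
#'   sits at `leg_length + torso_half_height` above ground.
#' @param n_legs 0 or 4.
#' @param neck_head_enabled logical; add the neck/head capsule.
#' @param head_pitch head elevation angle in radians.
#' @param tail_enabled,udder_enabled logical; add the tail capsule and the
#'   udder.
#' @param withers_bump_height bump height above the torso top, meters.
#' @param surface_detail_amp amplitude (m) of the fine-scale surface
#'   corrugation emulating folds, joints and scan texture of real animals;
#'   0 disables.
#' @param surface_detail_scale corrugation wavelength in meters.
#' @param chest_station_frac,abdomen_station_frac,shoulder_plane_frac,rump_plane_frac
#'   longitudinal station fractions in `[0, 1]`, strictly ordered
#'   rump < abdomen < chest < shoulder.
#' @param mesh_resolution subdivision level; grid spacing is
#'   `0.08 / mesh_resolution` meters.
#' @param seed integer; carried along for provenance (mesh construction
#'   itself is deterministic).
#' @return an object of class `cow_params`.
#' @export
cow_params <- function(torso_half_length = 0.84,
                       torso_half_width = 0.29,
                       torso_half_height = 0.405,
                       torso_shape_exponents = c(0.5, 0.25),
                       leg_length = 0.614,
                       leg_radius = 0.06,
                       n_legs = 4,
                       neck_head_enabled = TRUE,
                       head_pitch = 0.25,
                       tail_enabled = TRUE,
                       udder_enabled = TRUE,
                       withers_bump_height = 0.03,
                       surface_detail_amp = 0.0125,
                       surface_detail_scale = 0.12,
                       chest_station_frac = 0.66,
                       abdomen_station_frac = 0.45,
                       shoulder_plane_frac = 0.86,
                       rump_plane_frac = 0.04,
                       mesh_resolution = 4,
                       seed = 1L) {
  p <- list(torso_half_length = torso_half_length,
            torso_half_width = torso_half_width,
            torso_half_height = torso_half_height,
            torso_shape_exponents = torso_shape_exponents,
            leg_length = leg_length,
            leg_radius = leg_radius,
            n_legs = n_legs,
            neck_head_enabled = neck_head_enabled,
            head_pitch = head_pitch,
            tail_enabled = tail_enabled,
            udder_enabled = udder_enabled,
            withers_bump_height = withers_bump_height,
            surface_detail_amp = surface_detail_amp,
            surface_detail_scale = surface_detail_scale,
            chest_station_frac = chest_station_frac,
            abdomen_station_frac = abdomen_station_frac,
            shoulder_plane_frac = shoulder_plane_frac,
            rump_plane_frac = rump_plane_frac,
            mesh_resolution = mesh_resolution,
            seed = as.integer(seed))
  validate_cow_params(p)
  structure(p, class = "cow_params")
}

validate_cow_params <- function(p) {
  lengths <- c(p$torso_half_length, p$torso_half_width, p$torso_half_height,
               p$leg_length, p$leg_radius)
  if (any(lengths <= 0)) stop("all length parameters must be positive")
  if (length(p$torso_shape_exponents) != 2 ||
      any(p$torso_shape_exponents <= 0))
    stop("torso_shape_exponents must be two positive values")
  fr <- c(p$rump_plane_frac, p$abdomen_station_frac, p$chest_station_frac,
          p$shoulder_plane_frac)
  if (any(fr < 0) || any(fr > 1) || any(diff(fr) <= 0))
    stop("station fractions must be strictly ordered ",
         "rump < abdomen < chest < shoulder, within [0, 1]")
  if (!p$n_legs %in% c(0, 4)) stop("n_legs must be 0 or 4")
  if (p$mesh_resolution <= 0) stop("mesh_resolution must be positive")
  invisible(p)
}

#' @export
print.cow_params <- function(x, ...) {
  cat(sprintf(paste0(
    "cow_params: torso %.2f x %.2f x %.2f m (exponents %.2f/%.2f), ",
    "%d legs (%.2f m), head %s, resolution %g\n"),
    2 * x$torso_half_length, 2 * x$torso_half_width, 2 * x$torso_half_height,
    x$torso_shape_exponents[1], x$torso_shape_exponents[2], x$n_legs,
    x$leg_length, if (x$neck_head_enabled) "on" else "off",
    x$mesh_resolution))
  invisible(x)
}

#' Named presets for the synthetic herd
#'
#' `"adult"` targets an adult Holstein cow; `"heifer"` is the adult preset
#' under a uniform length scale chosen so the total volume matches a
#' growing-heifer cohort (about 580 L), `"ellipsoid"` disables legs, head
#' and bump with unit exponents for analytic ground truth.
#'
#' @param name preset name.
#' @param ... overrides passed to [cow_params()].
#' @return a `cow_params` object.
#' @export
cow_preset <- function(name = c("adult", "heifer", "ellipsoid"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    adult = cow_params(...),
    heifer = {
      s <- (581.2 / 763.9)^(1 / 3)
      scale_cow_params(cow_params(), s, ...)
    },
    ellipsoid = cow_params(torso_shape_exponents = c(1, 1), n_legs = 0,
                           neck_head_enabled = FALSE, tail_enabled = FALSE,
                           udder_enabled = FALSE,
                           withers_bump_height = 0,
                           surface_detail_amp = 0,
                           abdomen_station_frac = 0.5, ...))
  base
}

#' Uniformly scale all length parameters of a cow
#' @param params a `cow_params` object.
#' @param s scale factor.
#' @param ... further overrides applied after scaling.
#' @return scaled `cow_params`.
#' @export
scale_cow_params <- function(params, s, ...) {
  p <- unclass(params)
  for (f in c("torso_half_length", "torso_half_width", "torso_half_height",
              "leg_length", "leg_radius", "withers_bump_height",
              "surface_detail_amp", "surface_detail_scale"))
    p[[f]] <- p[[f]] * s
  over <- list(...)
  p[names(over)] <- over
  do.call(cow_params, p)
}

# x coordinate of a longitudinal station fraction
station_x <- function(params, frac) {
  -params$torso_half_length + frac * 2 * params$torso_half_length
}

# torso centre height above ground
torso_center_z <- function(params) {
  if (params$n_legs > 0) params$leg_length + params$torso_half_height
  else params$torso_half_height
}

# Implicit field of the cow body (negative inside), vectorised over points.
# `body_pitch` rotates the whole body about the y axis at the rear ground
# contact, emulating posture; callers re-ground the extracted mesh.
cow_field <- function(params, body_pitch = 0) {
  A <- params$torso_half_length
  B <- params$torso_half_width
  C <- params$torso_half_height
  zc <- torso_center_z(params)
  pc <- 2 / params$torso_shape_exponents[1]
  pp <- 2 / params$torso_shape_exponents[2]
  s_t <- min(B, C)
  bump <- params$withers_bump_height
  x_sh <- station_x(params, params$shoulder_plane_frac)
  pivot <- c(-A, 0, 0)

  function(p) {
    if (body_pitch != 0) {
      rot <- rotation_about("y", -body_pitch)
      p <- sweep(sweep(p, 2, pivot, "-") %*% t(rot), 2, pivot, "+")
    }
    x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
    u <- ((abs(y) / B)^pc + (abs(z - zc) / C)^pc)^(1 / pc)
    r <- (u^pp + (abs(x) / A)^pp)^(1 / pp)
    f <- (r - 1) * s_t

    if (params$n_legs > 0) {
      xl <- 0.62 * A
      yl <- 0.50 * B
      rl <- params$leg_radius
      ztop <- zc
      slant <- 0.2 * C  # hind cannon bones angle backward toward the hoof
      for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
        ax <- sx * xl - (if (sx < 0) slant * pmax(1 - z / ztop, 0) else 0)
        # pastern/hoof taper: the column narrows toward the ground
        rl_z <- rl * (0.75 + 0.25 * pmin(z / (0.3 * ztop), 1))
        radial <- sqrt((x - ax)^2 + (y - sy * yl)^2) - rl_z
        leg <- pmax(radial, z - ztop, -z)
        f <- smooth_min(f, leg)
      }
    }
    # appendage sizes are proportional to the torso half-height so that
    # uniform scaling of the length parameters scales the whole body
    if (isTRUE(params$neck_head_enabled)) {
      p0 <- c(0.88 * A, 0, zc + 0.35 * C)
      dirv <- c(cos(params$head_pitch), 0, sin(params$head_pitch))
      p1 <- p0 + 1.53 * C * dirv
      neck <- capsule_field(p, p0, p1, 0.272 * C)
      head <- ellipsoid_field(p, p1 + 0.247 * C * dirv,
                              C * c(0.395, 0.247, 0.296))
      f <- smooth_min(f, neck)
      f <- smooth_min(f, head)
    }
    if (isTRUE(params$tail_enabled)) {
      tail <- capsule_field(p, c(-A + 0.074 * C, 0, zc + 0.25 * C),
                            c(-A - 0.074 * C, 0, 0.5 * zc), 0.086 * C)
      f <- smooth_min(f, tail)
    }
    if (isTRUE(params$udder_enabled)) {
      ud <- ellipsoid_field(p, c(-0.42 * A, 0, zc - C + 0.02 * C),
                            C * c(0.42, 0.321, 0.30))
      f <- smooth_min(f, ud)
    }
    if (bump > 0) {
      u_sh <- (max(1 - (abs(x_sh) / A)^pp, 0))^(1 / pp)
      top <- zc + C * u_sh
      wb <- ellipsoid_field(p, c(x_sh, 0, top - bump),
                            c(0.494 * C, 0.6 * B, 2 * bump))
      f <- smooth_min(f, wb)
    }
    if (params$surface_detail_amp > 0) {
      # fine-scale corrugation emulating folds, joints and reconstruction
      # texture of real body scans (raises area, barely affects volume)
      w <- 2 * pi / params$surface_detail_scale
      f <- f + params$surface_detail_amp *
        sin(w * x) * sin(w * y) * sin(w * (z - zc))
    }
    f
  }
}

# Generous bounding box of the cow solid, for iso-surface extraction.
cow_bounds <- function(params) {
  A <- params$torso_half_length
  B <- params$torso_half_width
  C <- params$torso_half_height
  zc <- torso_center_z(params)
  head_reach <- if (isTRUE(params$neck_head_enabled)) 2.5 * C else 0.15 * C
  lower <- c(-A - 0.3 * C, -B - 0.2 * C, -0.02)
  upper <- c(A + head_reach, B + 0.2 * C,
             zc + C + params$withers_bump_height + 2.3 * C)
  list(lower = lower, upper = upper)
}

#' Generate a watertight cow mesh from parameters
#'
#' Extracts the zero level set of the implicit cow body with marching
#' tetrahedra. The mesh stands on the ground plane (minimum vertex height
#' 0), its longitudinal axis is x with the head toward +x, and it is
#' guaranteed watertight (construction fails otherwise).
#'
#' @param params a [cow_params()] object.
#' @param body_pitch whole-body pitch in radians (posture variation);
#'   the mesh is re-grounded after rotation.
#' @return a watertight [trimesh].
#' @export
make_cow_mesh <- function(params, body_pitch = 0) {
  validate_cow_params(params)
  h <- 0.08 / params$mesh_resolution
  b <- cow_bounds(params)
  mesh <- extract_isosurface(cow_field(params, body_pitch), b$lower, b$upper, h)
  mesh$vertices[, 3] <- mesh$vertices[, 3] - min(mesh$vertices[, 3])
  if (!is_watertight(mesh)) {
    stop(sprintf(
      "cow mesh construction produced a non-watertight mesh (%d open edges)",
      open_edge_count(mesh)))
  }
  mesh
}
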