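# Chain undirected segments (vertex-id pairs) into closed cycles. Vertices
# where the contour touches itself (figure-eight crossings) split the walk
# into simple cycles, so downstream capping/measurement always sees simple
# loops. Open chains are discarded.
chain_segments <- function(seg_a, seg_b) {
  nseg <- length(seg_a)
  adj <- list()
  for (s in seq_len(nseg)) {
    ka <- as.character(seg_a[s]); kb <- as.character(seg_b[s])
    adj[[ka]] <- c(adj[[ka]], s)
    adj[[kb]] <- c(adj[[kb]], s)
  }
  used <- logical(nseg)
  cycles <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    used[s0] <- TRUE
    path <- c(seg_a[s0], seg_b[s0])
    repeat {
      cur <- path[length(path)]
      cand <- adj[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) {
        if (length(path) >= 4 && path[1] == path[length(path)])
          cycles[[length(cycles) + 1L]] <- path[-length(path)]
        break
      }
      s <- cand[1]
      used[s] <- TRUE
      nxt <- if (seg_a[s] == cur) seg_b[s] else seg_a[s]
      hit <- match(nxt, path)
      if (!is.na(hit)) {
        cyc <- path[hit:length(path)]
        if (length(cyc) >= 3) cycles[[length(cycles) + 1L]] <- cyc
        path <- path[seq_len(hit)]
      } else {
        path <- c(path, nxt)
      }
    }
  }
  cycles
}

# Chain DIRECTED edges into directed cycles (Eulerian walk per component,
# splitting at revisited vertices). Used for cap loops, where the boundary
# direction is inherited from the mesh orientation.
chain_directed <- function(from, to) {
  out_adj <- list()
  for (s in seq_along(from)) {
    k <- as.character(from[s])
    out_adj[[k]] <- c(out_adj[[k]], s)
  }
  used <- logical(length(from))
  cycles <- list()
  for (s0 in seq_along(from)) {
    if (used[s0]) next
    used[s0] <- TRUE
    path <- c(from[s0], to[s0])
    repeat {
      cur <- path[length(path)]
      hit <- match(cur, path[-length(path)])
      if (!is.na(hit)) {
        cyc <- path[hit:(length(path) - 1L)]
        if (length(cyc) >= 3) cycles[[length(cycles) + 1L]] <- cyc
        path <- path[seq_len(hit)]
        if (length(path) == 1) break
        next
      }
      cand <- out_adj[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      s <- cand[1]
      used[s] <- TRUE
      path <- c(path, to[s])
    }
  }
  cycles
}

#' Planar cross-section of a mesh
#'
#' Intersects the mesh with the plane orthogonal to the longitudinal (x)
#' axis at `station` and chains the intersection segments into closed
#' polylines. The contour containing the dorsal-most (highest z) point is
#' flagged as the torso contour; other loops typically belong to legs.
#'
#' @param mesh a [trimesh].
#' @param station x coordinate of the cutting plane, meters.
#' @return object of class `cross_section`: list with `station`, `loops`
#'   (list of n x 3 point matrices, closed implicitly) and `torso` (index
#'   of the torso loop).
#' @export
cross_section <- function(mesh, station) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- v[, 1] - station
  d[abs(d) < 1e-12] <- 1e-12
  side <- d > 0
  s1 <- side[f[, 1]]; s2 <- side[f[, 2]]; s3 <- side[f[, 3]]
  crossing <- which(!(s1 == s2 & s2 == s3))
  if (length(crossing) == 0) stop("empty intersection at station ", station)

  pt_key <- character(0)
  pts <- list()
  key_of <- new.env(hash = TRUE)
  get_point <- function(i, j) {
    key <- if (i < j) paste(i, j) else paste(j, i)
    id <- key_of[[key]]
    if (!is.null(id)) return(id)
    t <- d[i] / (d[i] - d[j])
    pts[[length(pts) + 1L]] <<- v[i, ] + t * (v[j, ] - v[i, ])
    id <- length(pts)
    assign(key, id, envir = key_of)
    id
  }

  seg_a <- integer(0); seg_b <- integer(0)
  for (t in crossing) {
    tri <- f[t, ]
    ids <- integer(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- tri[e[1]]; j <- tri[e[2]]
      if (side[i] != side[j]) ids <- c(ids, get_point(i, j))
    }
    if (length(ids) == 2 && ids[1] != ids[2]) {
      seg_a <- c(seg_a, ids[1]); seg_b <- c(seg_b, ids[2])
    }
  }
  pts <- do.call(rbind, pts)

  cycles <- chain_segments(seg_a, seg_b)
  loops <- lapply(cycles, function(cy) pts[cy, , drop = FALSE])
  if (length(loops) == 0)
    stop("degenerate intersection at station ", station,
         " (no closed contour)")
  extent <- vapply(loops, function(L) max(dist(L[, 2:3])), numeric(1))
  loops <- loops[extent > 1e-6]
  if (length(loops) == 0)
    stop("degenerate (tangent) intersection at station ", station)
  zmax <- vapply(loops, function(L) max(L[, 3]), numeric(1))
  structure(list(station = station, loops = loops,
                 torso = which.max(zmax)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross_section at x = %.3f m: %d closed contour(s), torso = #%d\n",
              x$station, length(x$loops), x$torso))
  invisible(x)
}

polyline_length <- function(pts, closed = TRUE) {
  p2 <- if (closed) rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
        else pts[-1, , drop = FALSE]
  p1 <- if (closed) pts else pts[-nrow(pts), , drop = FALSE]
  sum(sqrt(rowSums((p2 - p1)^2)))
}

#' Girth of a cross-section (taut-tape circumference)
#'
#' Perimeter of the planar convex hull of the torso contour: the convex
#' hull emulates a measuring tape, which bridges concavities. The raw
#' contour length is attached as attribute `raw_length` for diagnostics.
#'
#' @param section a [cross_section].
#' @return girth in meters.
#' @export
girth <- function(section) {
  loop <- section$loops[[section$torso]]
  yz <- loop[, 2:3, drop = FALSE]
  h <- grDevices::chull(yz)
  hull <- yz[h, , drop = FALSE]
  per <- polyline_length(cbind(0, hull), closed = TRUE)
  structure(per, raw_length = polyline_length(loop, closed = TRUE))
}

# Clip a mesh by the plane x = x0, keeping the requested side, and cap the
# opening with planar triangle fans. Vertices within 1e-9 of the plane are
# snapped to the lower side so complementary clips partition the solid.
clip_halfspace <- function(mesh, x0, keep = c("below", "above")) {
  keep <- match.arg(keep)
  v <- mesh$vertices
  f <- mesh$faces
  d <- v[, 1] - x0
  d[abs(d) < 1e-9] <- -1e-9
  inside <- if (keep == "below") d < 0 else d > 0

  n_in <- inside[f[, 1]] + inside[f[, 2]] + inside[f[, 3]]
  keep_faces <- f[n_in == 3L, , drop = FALSE]
  mixed <- which(n_in == 1L | n_in == 2L)

  new_pts <- list()
  key_of <- new.env(hash = TRUE)
  nv0 <- nrow(v)
  cut_point <- function(i, j) {
    key <- if (i < j) paste(i, j) else paste(j, i)
    id <- key_of[[key]]
    if (!is.null(id)) return(id)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    p[1] <- x0
    new_pts[[length(new_pts) + 1L]] <<- p
    id <- nv0 + length(new_pts)
    assign(key, id, envir = key_of)
    id
  }

  extra_faces <- list()
  cap_from <- integer(0); cap_to <- integer(0)
  for (t in mixed) {
    tri <- f[t, ]
    poly <- integer(0)
    for (e in 1:3) {
      i <- tri[e]; j <- tri[if (e == 3) 1 else e + 1]
      if (inside[i]) poly <- c(poly, i)
      if (inside[i] != inside[j]) poly <- c(poly, cut_point(i, j))
    }
    np <- length(poly)
    if (np >= 3) {
      for (k in 2:(np - 1))
        extra_faces[[length(extra_faces) + 1L]] <-
          c(poly[1], poly[k], poly[k + 1])
      # the directed on-plane boundary edge of this polygon (cyclic pair of
      # two consecutive cut vertices), direction inherited from the face
      # orientation so cap winding follows automatically
      for (k in 1:np) {
        a <- poly[k]; b <- poly[if (k == np) 1 else k + 1]
        if (a > nv0 && b > nv0 && a != b) {
          cap_from <- c(cap_from, a); cap_to <- c(cap_to, b)
        }
      }
    }
  }

  v_all <- rbind(v, do.call(rbind, new_pts))
  faces <- rbind(keep_faces,
                 if (length(extra_faces)) do.call(rbind, extra_faces))

  if (length(cap_from) > 0) {
    # where the plane grazes a fold, two polygons share the cut edge with
    # opposite directions: the surface is already closed there, so the
    # pair annihilates and no cap is placed over it
    fwd <- paste(cap_from, cap_to)
    rev_ <- paste(cap_to, cap_from)
    drop_seg <- fwd %in% rev_
    cap_from <- cap_from[!drop_seg]; cap_to <- cap_to[!drop_seg]
  }
  if (length(cap_from) > 0) {
    for (loop in chain_directed(cap_from, cap_to)) {
      if (length(loop) < 3) next
      centroid <- colMeans(v_all[loop, , drop = FALSE])
      centroid[1] <- x0
      v_all <- rbind(v_all, centroid)
      ci <- nrow(v_all)
      nl <- length(loop)
      # boundary edge (v_i -> v_{i+1}) is matched by cap edge going back
      faces <- rbind(faces, cbind(ci, loop[c(2:nl, 1)], loop))
    }
  }
  drop_degenerate_faces(trimesh(v_all, faces))
}

#' Partial body between the rump and shoulder cutting planes
#'
#' Clips the mesh to the region between the two planes orthogonal to the
#' longitudinal axis (head/neck and tail region removed) and caps the
#' openings so the result is watertight. Partial volume and surface are
#' then plain [mesh_volume()] / [mesh_area()] of the result.
#'
#' @param mesh a watertight [trimesh].
#' @param shoulder_plane,rump_plane x coordinates (m) of the cutting
#'   planes, `rump_plane < shoulder_plane`.
#' @return a watertight [trimesh] of the partial body.
#' @export
clip_partial_body <- function(mesh, shoulder_plane, rump_plane) {
  if (rump_plane >= shoulder_plane)
    stop("rump_plane must be below shoulder_plane")
  xr <- range(mesh$vertices[, 1])
  if (rump_plane <= xr[1] && shoulder_plane >= xr[2]) {
    warning("cutting planes lie outside the mesh extent; returning full mesh")
    return(mesh)
  }
  # a cutting plane can graze a vertex or a fold pinch of the surface and
  # produce a non-manifold cut contour; retry with a sub-voxel plane nudge
  for (off in c(0, 0.0015, -0.0015, 0.003)) {
    out <- mesh
    if (shoulder_plane < xr[2])
      out <- clip_halfspace(out, shoulder_plane + off, "below")
    if (rump_plane > xr[1])
      out <- clip_halfspace(out, rump_plane - off, "above")
    if (is_watertight(out)) return(out)
  }
  stop("partial-body clip produced a non-watertight mesh (",
       open_edge_count(out), " open edges)")
}

trait_names <- c("WH", "HW", "WB", "CD", "HG", "AC", "DL",
                 "PS", "TS", "PV", "TV")

#' Measure all morphological traits of a mesh
#'
#' Computes the nine morphological traits plus partial and total volume and
#' surface from a watertight mesh and its feature points. The body frame is
#' derived from the landmarks ([body_frame()]), so all traits are invariant
#' under rigid motion of mesh and landmarks together. Definitions: WH is the
#' height of the withers landmark above the ground plane (lowest mesh
#' point); HW and WB the distances between hip and pin landmarks; DL the
#' mean of the left/right buttock-tip-to-shoulder-tip distances; CD the
#' vertical extent of the torso contour at the chest station; HG and AC the
#' taut-tape girths at the chest and abdomen stations; PV/PS the volume and
#' surface of the body clipped between rump and shoulder planes; TV/TS the
#' full-mesh volume and surface.
#'
#' Missing landmarks yield `NA` for the affected traits (with a warning);
#' the remaining traits are still computed.
#'
#' @param mesh a watertight [trimesh].
#' @param fp a [feature_points] object.
#' @return named numeric `trait_vector`: WH, HW, WB, CD, HG, AC, DL in m;
#'   PS, TS in m^2; PV, TV in m^3.
#' @export
measure_all <- function(mesh, fp) {
  frame <- body_frame(fp)
  rot <- rbind(frame$x, frame$y, frame$z)
  vc <- mesh$vertices %*% t(rot)
  mesh_c <- trimesh(vc, mesh$faces)
  lm <- fp$landmarks %*% t(rot)
  rownames(lm) <- rownames(fp$landmarks)
  st <- as.numeric(fp$stations %*% frame$x)
  names(st) <- rownames(fp$stations)

  out <- stats::setNames(rep(NA_real_, length(trait_names)), trait_names)
  has <- function(...) all(c(...) %in% rownames(lm))
  dist3 <- function(a, b) sqrt(sum((lm[a, ] - lm[b, ])^2))

  ground <- min(vc[, 3])
  if (has("withers")) out["WH"] <- lm["withers", 3] - ground
  if (has("hip_left", "hip_right")) out["HW"] <- dist3("hip_left", "hip_right")
  if (has("pin_left", "pin_right")) out["WB"] <- dist3("pin_left", "pin_right")
  if (has("buttock_tip_left", "shoulder_tip_left",
          "buttock_tip_right", "shoulder_tip_right"))
    out["DL"] <- (dist3("buttock_tip_left", "shoulder_tip_left") +
                  dist3("buttock_tip_right", "shoulder_tip_right")) / 2

  chest <- cross_section(mesh_c, st[["chest_station"]])
  torso_loop <- chest$loops[[chest$torso]]
  out["CD"] <- max(torso_loop[, 3]) - min(torso_loop[, 3])
  out["HG"] <- as.numeric(girth(chest))
  out["AC"] <- as.numeric(girth(cross_section(mesh_c, st[["abdomen_station"]])))

  out["TV"] <- mesh_volume(mesh_c)
  out["TS"] <- mesh_area(mesh_c)
  partial <- clip_partial_body(mesh_c, st[["shoulder_plane"]],
                               st[["rump_plane"]])
  out["PV"] <- mesh_volume(partial)
  out["PS"] <- mesh_area(partial)

  if (anyNA(out))
    warning("missing landmarks; traits not computed: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  structure(out, class = "trait_vector")
}

#' @export
print.trait_vector <- function(x, ...) {
  cat("trait_vector:\n")
  units <- c(WH = "m", HW = "m", WB = "m", CD = "m", HG = "m", AC = "m",
             DL = "m", PS = "m2", TS = "m2", PV = "m3", TV = "m3")
  for (n in names(units)) {
    if (!n %in% names(x)) next
    extra <- if (units[n] == "m3" && is.finite(x[n]))
      sprintf(" (%.1f L)", 1000 * x[n]) else ""
    cat(sprintf("  %-3s %10.4f %-3s%s\n", n, unname(x[n]), units[n], extra))
  }
  invisible(x)
}

#' @export
as.data.frame.trait_vector <- function(x, ...) {
  units <- c(WH = "m", HW = "m", WB = "m", CD = "m", HG = "m", AC = "m",
             DL = "m", PS = "m2", TS = "m2", PV = "m3", TV = "m3")
  data.frame(trait = names(unclass(x)), value = as.numeric(x),
             unit = unname(units[names(unclass(x))]),
             stringsAsFactors = FALSE)
}

#' Validate plausibility invariants of a trait vector
#'
#' Checks positivity, `PV <= TV`, `PS <= TS` and `CD < WH`; returns TRUE
#' invisibly or signals a warning describing the violated invariant.
#'
#' @param traits a `trait_vector`.
#' @return logical, invisibly.
#' @export
validate_traits <- function(traits) {
  ok <- TRUE
  x <- unclass(traits)
  if (any(x[!is.na(x)] <= 0)) {
    warning("non-positive trait value(s)"); ok <- FALSE
  }
  chk <- function(cond, msg) {
    if (isTRUE(cond)) { warning(msg); ok <<- FALSE }
  }
  chk(!is.na(x["PV"]) && !is.na(x["TV"]) && x["PV"] > x["TV"] * (1 + 1e-9),
      "PV exceeds TV")
  chk(!is.na(x["PS"]) && !is.na(x["TS"]) && x["PS"] > x["TS"] * (1 + 1e-9),
      "PS exceeds TS")
  chk(!is.na(x["CD"]) && !is.na(x["WH"]) && x["CD"] >= x["WH"],
      "CD not smaller than WH")
  invisible(ok)
}

#' Analytic/reference ground-truth traits for a parametric cow
#'
#' Traits with closed forms (pure ellipsoid body: total volume, chest
#' depth, girths from the elliptic perimeter) are computed analytically;
#' all others are measured on a reference mesh at twice the working
#' resolution with noise-free landmarks. Deterministic for fixed params.
#'
#' @param params a [cow_params()] object.
#' @return a `trait_vector`.
#' @export
true_traits <- function(params) {
  ref <- params
  ref$mesh_resolution <- params$mesh_resolution * 2
  class(ref) <- "cow_params"
  mesh <- make_cow_mesh(ref)
  tv <- measure_all(mesh, cow_landmarks(mesh, ref))

  pure_ellipsoid <- all(params$torso_shape_exponents == c(1, 1)) &&
    params$n_legs == 0 && !isTRUE(params$neck_head_enabled) &&
    !isTRUE(params$tail_enabled) && !isTRUE(params$udder_enabled) &&
    params$withers_bump_height == 0 && params$surface_detail_amp == 0
  if (pure_ellipsoid) {
    A <- params$torso_half_length
    B <- params$torso_half_width
    C <- params$torso_half_height
    u <- function(frac) sqrt(pmax(1 - (station_x(params, frac) / A)^2, 0))
    tv["TV"] <- 4 / 3 * pi * A * B * C
    tv["CD"] <- 2 * C * u(params$chest_station_frac)
    tv["HG"] <- ellipse_perimeter(B * u(params$chest_station_frac),
                                  C * u(params$chest_station_frac))
    tv["AC"] <- ellipse_perimeter(B * u(params$abdomen_station_frac),
                                  C * u(params$abdomen_station_frac))
  }
  tv
}
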