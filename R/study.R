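#' Noise model for synthetic studies
#'
#' Three independent noise layers: landmark re-identification jitter (the
#' human "click" error, acting within a single acquisition and therefore
#' driving repeatability), posture variation between acquisition sessions
#' (head pitch and stance shift, driving reproducibility), and optional
#' per-vertex surface noise. Jitter never changes the mesh; posture never
#' varies within a session.
#'
#' @param click_jitter_sd landmark jitter SD in meters (isotropic).
#' @param posture_pitch_sd between-session head-pitch SD in radians.
#' @param posture_shift_sd between-session stance (leg length) SD in meters.
#' @param surface_noise_sd per-vertex normal-direction noise SD in meters.
#' @param seed master seed; per-record seeds are derived by counter
#'   splitting so every record is independently reproducible.
#' @return a `noise_model` object.
#' @export
noise_model <- function(click_jitter_sd = 0.006, posture_pitch_sd = 0.03,
                        posture_shift_sd = 0.008, surface_noise_sd = 0,
                        seed = 1L) {
  if (any(c(click_jitter_sd, posture_pitch_sd, posture_shift_sd,
            surface_noise_sd) < 0))
    stop("noise SDs must be non-negative")
  structure(list(click_jitter_sd = click_jitter_sd,
                 posture_pitch_sd = posture_pitch_sd,
                 posture_shift_sd = posture_shift_sd,
                 surface_noise_sd = surface_noise_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Study designs for device validation
#'
#' @param kind one of `repeatability` (one acquisition, repeated point
#'   identification), `reproducibility` (several acquisition sessions),
#'   `comparison`, `bw_cohort`.
#' @param n_subjects number of animals.
#' @param n_sessions acquisition sessions per animal (1 for repeatability).
#' @param n_repeats point-identification repeats per session.
#' @param noise a [noise_model()].
#' @return a `study_design` object.
#' @export
study_design <- function(kind = c("repeatability", "reproducibility",
                                  "comparison", "bw_cohort"),
                         n_subjects, n_sessions = 1, n_repeats = 1,
                         noise = noise_model()) {
  kind <- match.arg(kind)
  if (kind == "repeatability" && n_sessions != 1)
    stop("repeatability designs have a single session")
  if (kind == "reproducibility" && n_sessions <= 1)
    stop("reproducibility designs need more than one session")
  if (n_subjects < 1 || n_sessions < 1 || n_repeats < 1)
    stop("counts must be positive")
  structure(list(kind = kind, n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_repeats = as.integer(n_repeats), noise = noise),
            class = "study_design")
}

# counter-based seed splitting (kept well below 2^31)
record_seed <- function(master, s, j, k = 0) {
  as.integer((master %% 100000L) * 19013L +
             ((s * 211L + j) * 211L + k) %% 19013L)
}

perturb_posture <- function(params, noise, seed) {
  set.seed(seed)
  dp <- stats::rnorm(1, 0, noise$posture_pitch_sd)
  dz <- stats::rnorm(1, 0, noise$posture_shift_sd)
  p <- unclass(params)
  p$head_pitch <- p$head_pitch + dp
  p$leg_length <- max(p$leg_length + dz, 0.05)
  p <- do.call(cow_params, p)
  # head movement shifts weight bearing: mild whole-body pitch (lever model)
  list(params = p, body_pitch = 0.15 * dp)
}

jitter_feature_points <- function(fp, sd, seed) {
  if (sd == 0) return(fp)
  set.seed(seed)
  lm <- fp$landmarks + matrix(stats::rnorm(length(fp$landmarks), 0, sd),
                              nrow(fp$landmarks), 3)
  st <- fp$stations
  st[, 1] <- st[, 1] + stats::rnorm(nrow(st), 0, sd)
  rownames(st) <- rownames(fp$stations)
  feature_points(lm, st)
}

apply_surface_noise <- function(mesh, sd, seed) {
  if (sd == 0) return(mesh)
  set.seed(seed)
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2], ] - v[f[, 1], ]
  ac <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  vn <- matrix(0, nrow(v), 3)
  for (c_ in 1:3) {
    for (d in 1:3) {
      agg <- rowsum(fn[, d], f[, c_])
      idx <- as.integer(rownames(agg))
      vn[idx, d] <- vn[idx, d] + agg
    }
  }
  vn <- vn / pmax(sqrt(rowSums(vn^2)), 1e-12)
  trimesh(v + vn * stats::rnorm(nrow(v), 0, sd), f)
}

#' Generate the per-record inputs of a validation study
#'
#' Instantiates a study design on a set of base animals: per (subject,
#' session) a posture-perturbed mesh with its exact landmarks, and per
#' repeat a jittered copy of the landmarks. Within a (subject, session)
#' pair the mesh is identical and only landmark jitter differs; posture
#' varies only across sessions. Fully reproducible from the noise seed.
#'
#' @param design a [study_design()].
#' @param base_params list of [cow_params()], one per subject.
#' @return a `measurement_inputs` object: `records` data.frame
#'   (subject_id, session, rep, mesh_id), `meshes` (named list of
#'   [trimesh]), `landmarks` (list of [feature_points], one per record,
#'   in `records` row order) and `true_fp` (noise-free landmarks per mesh).
#' @export
generate_study <- function(design, base_params) {
  if (length(base_params) != design$n_subjects)
    stop("length of base_params must equal n_subjects")
  noise <- design$noise
  meshes <- list()
  true_fp <- list()
  rec <- list()
  fps <- list()
  for (s in seq_len(design$n_subjects)) {
    for (j in seq_len(design$n_sessions)) {
      mesh_id <- sprintf("s%02d_j%02d", s, j)
      sseed <- record_seed(noise$seed, s, j)
      if (design$n_sessions > 1 &&
          (noise$posture_pitch_sd > 0 || noise$posture_shift_sd > 0)) {
        post <- perturb_posture(base_params[[s]], noise, sseed)
      } else {
        post <- list(params = base_params[[s]], body_pitch = 0)
      }
      mesh <- make_cow_mesh(post$params, body_pitch = post$body_pitch)
      mesh <- apply_surface_noise(mesh, noise$surface_noise_sd,
                                  sseed + 7L)
      meshes[[mesh_id]] <- mesh
      fp0 <- cow_landmarks(mesh, post$params)
      true_fp[[mesh_id]] <- fp0
      for (k in seq_len(design$n_repeats)) {
        fp <- jitter_feature_points(fp0, noise$click_jitter_sd,
                                    record_seed(noise$seed, s, j, k))
        rec[[length(rec) + 1L]] <- data.frame(
          subject_id = sprintf("cow%02d", s), session = j, rep = k,
          mesh_id = mesh_id, stringsAsFactors = FALSE)
        fps[[length(fps) + 1L]] <- fp
      }
    }
  }
  records <- do.call(rbind, rec)
  stopifnot(nrow(records) ==
            design$n_subjects * design$n_sessions * design$n_repeats)
  structure(list(design = design, records = records, meshes = meshes,
                 landmarks = fps, true_fp = true_fp),
            class = "measurement_inputs")
}

#' @export
print.measurement_inputs <- function(x, ...) {
  cat(sprintf("measurement_inputs: %s design, %d records (%d x %d x %d), %d meshes\n",
              x$design$kind, nrow(x$records), x$design$n_subjects,
              x$design$n_sessions, x$design$n_repeats, length(x$meshes)))
  invisible(x)
}

#' Measure every record of a study
#'
#' Runs [measure_all()] on each record's mesh with its (jittered)
#' landmarks and returns the long-format measurement table. Complete
#' volume and surface in the table are derived from the partial measures
#' via the published conversion equations, so point-identification noise
#' propagates into them the same way it does in the device workflow.
#'
#' @param inputs a `measurement_inputs` object from [generate_study()].
#' @param config a [prediction_config()] for the partial-to-total
#'   equations.
#' @return a [measurement_table()].
#' @export
measure_study <- function(inputs, config = prediction_config()) {
  units <- c(WH = "m", HW = "m", WB = "m", CD = "m", HG = "m", AC = "m",
             DL = "m", PS = "m2", TS = "m2", PV = "m3", TV = "m3")
  rows <- vector("list", nrow(inputs$records))
  for (i in seq_len(nrow(inputs$records))) {
    r <- inputs$records[i, ]
    tv <- measure_all(inputs$meshes[[r$mesh_id]], inputs$landmarks[[i]])
    tv["TV"] <- total_volume_from_partial(tv[["PV"]], config)
    tv["TS"] <- total_surface_from_partial(tv[["PS"]], config)
    rows[[i]] <- data.frame(subject_id = r$subject_id, session = r$session,
                            rep = r$rep, trait = names(unclass(tv)),
                            value = as.numeric(tv),
                            unit = unname(units[names(unclass(tv))]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  measurement_table(out$subject_id, out$session, out$rep, out$trait,
                    out$value, out$unit)
}

#' Scale weight of a synthetic animal
#'
#' The weigh-bridge reading of a synthetic animal: the published equation
#' applied to its traits plus a Gaussian residual. With `residual_sd = 0`
#' this equals [predict_bw()] exactly.
#'
#' @param traits a `trait_vector` (needs TV, HW, WB).
#' @param residual_sd residual SD in kg.
#' @param seed integer seed for the residual draw.
#' @param config a [prediction_config()].
#' @return weight in kg.
#' @export
scale_weight <- function(traits, residual_sd = 0, seed = 1L,
                         config = prediction_config()) {
  if (residual_sd < 0) stop("residual_sd must be non-negative")
  bw <- predict_bw(traits[["TV"]], traits[["HW"]], traits[["WB"]], config)
  if (residual_sd > 0) {
    set.seed(as.integer(seed))
    bw <- bw + stats::rnorm(1, 0, residual_sd)
  }
  bw
}

#' Parameter sets for a synthetic fleet of animals
#'
#' Animals drawn around a preset by a per-animal uniform length scale
#' (similarity scaling preserves all trait ratios, keeping the fleet
#' within breed-realistic proportions).
#'
#' @param n number of animals.
#' @param preset preset name for [cow_preset()].
#' @param size_cv coefficient of variation of the length scale.
#' @param seed integer seed.
#' @param ... overrides passed to [cow_preset()].
#' @return list of `cow_params`.
#' @export
fleet_params <- function(n, preset = "adult", size_cv = 0.035, seed = 1L,
                         ...) {
  set.seed(as.integer(seed))
  scales <- stats::rnorm(n, 1, size_cv)
  base <- cow_preset(preset, ...)
  lapply(seq_len(n), function(i)
    scale_cow_params(base, max(scales[i], 0.5), seed = seed + i))
}
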