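# Lazily computed, memoized fixtures shared across test files. Everything
# is generated in code; the cache lives for one test session.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    val <- switch(name,
      # adult preset at working test resolution, with landmarks and traits
      adult = {
        p <- cow_params(mesh_resolution = 2.5)
        m <- make_cow_mesh(p)
        fp <- cow_landmarks(m, p)
        list(params = p, mesh = m, fp = fp,
             traits = suppressWarnings(measure_all(m, fp)))
      },
      # pure ellipsoid preset (analytic ground truth available)
      ellipsoid = {
        p <- cow_preset("ellipsoid")
        m <- make_cow_mesh(p)
        list(params = p, mesh = m, fp = cow_landmarks(m, p),
             truth = true_traits(p))
      },
      # small noise-free study (identical records per subject)
      quiet_study = {
        pars <- fleet_params(2, "adult", size_cv = 0.02, seed = 11,
                             mesh_resolution = 1.6)
        des <- study_design("repeatability", 2, 1, 3,
                            noise_model(0, 0, 0, 0, seed = 11))
        st <- generate_study(des, pars)
        list(study = st, table = measure_study(st))
      },
      # sixteen-animal fleet with measured traits (herd calibration checks)
      fleet16 = {
        pars <- fleet_params(16, "adult", seed = 99, mesh_resolution = 3)
        traits <- vapply(pars, function(p) {
          m <- make_cow_mesh(p)
          unclass(suppressWarnings(measure_all(m, cow_landmarks(m, p))))
        }, numeric(11))
        list(params = pars, traits = traits)
      },
      stop("unknown fixture: ", name))
    assign(name, val, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# icosphere rotated so one vertex sits exactly on the -z axis (used for
# exact center-pixel depth checks)
axis_aligned_sphere <- function(radius = 1, subdivisions = 4,
                                center = c(0, 0, 0)) {
  m <- icosphere(radius, subdivisions)
  v1 <- m$vertices[1, ] / sqrt(sum(m$vertices[1, ]^2))
  target <- c(0, 0, -1)
  ax <- c(v1[2] * target[3] - v1[3] * target[2],
          v1[3] * target[1] - v1[1] * target[3],
          v1[1] * target[2] - v1[2] * target[1])
  s <- sqrt(sum(ax^2))
  c_ <- sum(v1 * target)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + K + K %*% K * ((1 - c_) / s^2)
  transform_mesh(m, rotation = R, translation = center)
}

# pooled within-group SD computed by hand (oracle for residual_sd)
pooled_sd_oracle <- function(values, groups) {
  ss <- 0; n <- 0; k <- 0
  for (g in unique(groups)) {
    x <- values[groups == g]
    ss <- ss + sum((x - mean(x))^2)
    n <- n + length(x)
    k <- k + 1
  }
  sqrt(ss / (n - k))
}
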