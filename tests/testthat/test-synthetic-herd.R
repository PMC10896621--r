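test_that("ellipsoid degenerate body matches the closed-form volume", {
  fx <- fixture("ellipsoid")
  p <- fx$params
  expect_true(is_watertight(fx$mesh))
  exact <- 4 / 3 * pi * p$torso_half_length * p$torso_half_width *
    p$torso_half_height
  expect_lt(abs(mesh_volume(fx$mesh) / exact - 1), 0.005)
})

test_that("default adult preset falls in the herd-scale envelope", {
  fx <- fixture("adult")
  tv <- fx$traits
  expect_gt(tv[["TV"]], 0.50)
  expect_lt(tv[["TV"]], 0.80)
  expect_gt(tv[["WH"]], 1.35)
  expect_lt(tv[["WH"]], 1.55)
  expect_equal(min(fx$mesh$vertices[, 3]), 0)
  expect_true(validate_traits(tv))
})

test_that("uniform length scaling scales volume cubically and traits linearly", {
  p1 <- cow_params(mesh_resolution = 4, surface_detail_amp = 0)
  p2 <- scale_cow_params(p1, 2)
  m1 <- make_cow_mesh(p1)
  m2 <- make_cow_mesh(p2)
  expect_lt(abs(mesh_volume(m2) / mesh_volume(m1) / 8 - 1), 0.005)
  expect_lt(abs(mesh_area(m2) / mesh_area(m1) / 4 - 1), 0.005)
  t1 <- suppressWarnings(measure_all(m1, cow_landmarks(m1, p1)))
  t2 <- suppressWarnings(measure_all(m2, cow_landmarks(m2, p2)))
  for (tr in c("WH", "HW", "CD", "AC"))
    expect_lt(abs(t2[[tr]] / t1[[tr]] / 2 - 1), 0.005)
})

test_that("ground-truth traits match analytic oracles on the ellipsoid", {
  fx <- fixture("ellipsoid")
  p <- fx$params
  C <- p$torso_half_height
  B <- p$torso_half_width
  A <- p$torso_half_length
  u <- function(frac) sqrt(1 - (2 * frac - 1)^2)
  tt <- fx$truth
  expect_equal(tt[["CD"]], 2 * C * u(p$chest_station_frac))
  # abdomen station sits at mid-body: perimeter of the (B, C) ellipse,
  # checked against independent adaptive quadrature of the arc length
  oracle <- 4 * integrate(function(t) sqrt((B * sin(t))^2 + (C * cos(t))^2),
                          0, pi / 2, rel.tol = 1e-10)$value
  expect_lt(abs(tt[["AC"]] / oracle - 1), 0.001)
  expect_equal(tt[["TV"]], 4 / 3 * pi * A * B * C)
})

test_that("measured traits agree with ground truth on the ellipsoid", {
  fx <- fixture("ellipsoid")
  mm <- suppressWarnings(measure_all(fx$mesh, fx$fp))
  for (tr in c("WH", "HW", "WB", "CD", "HG", "AC", "DL", "PS", "TS",
               "PV", "TV"))
    expect_lt(abs(mm[[tr]] / fx$truth[[tr]] - 1), 0.01)
})

test_that("ground truth is self-consistent on the default preset", {
  p <- cow_params(mesh_resolution = 1.5)
  tt <- true_traits(p)
  ref <- p
  ref$mesh_resolution <- p$mesh_resolution * 2
  class(ref) <- "cow_params"
  m <- make_cow_mesh(ref)
  mm <- suppressWarnings(measure_all(m, cow_landmarks(m, ref)))
  for (tr in names(unclass(tt)))
    expect_lt(abs(mm[[tr]] / tt[[tr]] - 1), 0.01)
})

test_that("study generation emits exactly n_subjects x n_sessions x n_repeats records", {
  pars <- fleet_params(8, "adult", seed = 21, mesh_resolution = 1.2)
  rp <- generate_study(study_design("repeatability", 8, 1, 5,
                                    noise_model(seed = 21)), pars)
  expect_identical(nrow(rp$records), 40L)
  ri <- generate_study(study_design("reproducibility", 8, 5, 5,
                                    noise_model(seed = 21)), pars)
  expect_identical(nrow(ri$records), 200L)
  expect_identical(length(ri$meshes), 40L)
  # within a (subject, session) pair the mesh is shared; across sessions
  # the posture-perturbed meshes differ
  ids <- unique(ri$records[ri$records$subject_id == "cow01", "mesh_id"])
  expect_identical(length(ids), 5L)
  expect_false(identical(ri$meshes[[ids[1]]]$vertices,
                         ri$meshes[[ids[2]]]$vertices))
})

test_that("study generation validates designs and inputs", {
  expect_error(study_design("repeatability", 8, 2, 5), "single session")
  expect_error(study_design("reproducibility", 8, 1, 5), "more than one")
  pars <- fleet_params(2, "adult", seed = 1, mesh_resolution = 1.2)
  expect_error(generate_study(study_design("repeatability", 3, 1, 2,
                                           noise_model(seed = 1)), pars),
               "n_subjects")
})

test_that("zero noise gives identical records and zero downstream CVs", {
  fx <- fixture("quiet_study")
  lm1 <- fx$study$landmarks[[1]]$landmarks
  lm2 <- fx$study$landmarks[[2]]$landmarks
  expect_identical(lm1, lm2)
  a <- assess(fx$table)
  expect_true(all(a$cv_percent < 1e-9))
  expect_true(all(a$verdict_below_4pct))
})

test_that("studies are bit-reproducible from the seed", {
  pars <- fleet_params(2, "adult", seed = 31, mesh_resolution = 1.2)
  des <- study_design("reproducibility", 2, 2, 2, noise_model(seed = 31))
  s1 <- generate_study(des, pars)
  s2 <- generate_study(des, pars)
  expect_identical(s1$meshes, s2$meshes)
  expect_identical(s1$landmarks, s2$landmarks)
})

test_that("scale weight equals the published equation when noise-free", {
  tr <- structure(c(TV = 0.5812, HW = 0.507, WB = 0.507),
                  class = "trait_vector")
  expect_equal(scale_weight(tr, residual_sd = 0),
               644 * 0.5812 + 408 * 0.507 + 271 * 0.507 - 199)
  zero <- structure(c(TV = 0, HW = 0, WB = 0), class = "trait_vector")
  expect_warning(bw0 <- scale_weight(zero, residual_sd = 0), "plausible")
  expect_equal(bw0, -199)
})

test_that("scale weights regress on predictions with unit slope and high R2", {
  pars <- fleet_params(13, "heifer", size_cv = 0.05, seed = 41,
                       mesh_resolution = 1.6)
  traits <- lapply(pars, function(p) {
    m <- make_cow_mesh(p)
    tv <- suppressWarnings(measure_all(m, cow_landmarks(m, p)))
    tv["TV"] <- total_volume_from_partial(tv[["PV"]])
    tv
  })
  predicted <- vapply(traits, function(tv)
    predict_bw(tv[["TV"]], tv[["HW"]], tv[["WB"]]), numeric(1))
  slopes <- r2s <- numeric(100)
  for (s in 1:100) {
    scale_kg <- vapply(seq_along(traits), function(i)
      scale_weight(traits[[i]], residual_sd = 5, seed = s * 1000 + i),
      numeric(1))
    fit <- validate_bw(predicted, scale_kg)
    slopes[s] <- fit$slope
    r2s[s] <- fit$r_squared
  }
  expect_lt(abs(mean(slopes) - 1), 0.05)
  expect_gte(mean(r2s >= 0.95), 0.9)
})
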