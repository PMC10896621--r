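test_that("partial-body clipping reproduces the analytic cylinder volume", {
  cy <- cylinder_mesh(radius = 0.5, length_x = 2, n_segments = 128)
  mid <- clip_partial_body(cy, shoulder_plane = 0.5, rump_plane = -0.5)
  expect_true(is_watertight(mid))
  expect_lt(abs(mesh_volume(mid) / (pi * 0.25) - 1), 0.005)
})

test_that("clipping with planes beyond the extent is a no-op with warning", {
  fx <- fixture("adult")
  expect_warning(out <- clip_partial_body(fx$mesh, 10, -10), "outside")
  expect_equal(mesh_volume(out), mesh_volume(fx$mesh))
  expect_error(clip_partial_body(fx$mesh, -0.5, 0.5), "below")
})

test_that("single-plane clips conserve volume exactly", {
  fx <- fixture("adult")
  v0 <- mesh_volume(fx$mesh)
  for (x0 in c(-0.55, 0.05, 0.48)) {
    lo <- bovimorph:::clip_halfspace(fx$mesh, x0, "below")
    hi <- bovimorph:::clip_halfspace(fx$mesh, x0, "above")
    expect_true(is_watertight(lo))
    expect_true(is_watertight(hi))
    expect_lt(abs((mesh_volume(lo) + mesh_volume(hi)) / v0 - 1), 1e-6)
  }
})

test_that("partial measures never exceed totals on generated cows", {
  for (s in 1:3) {
    p <- fleet_params(1, "adult", seed = 50 + s,
                      mesh_resolution = 1.6)[[1]]
    m <- make_cow_mesh(p)
    tv <- suppressWarnings(measure_all(m, cow_landmarks(m, p)))
    expect_lte(tv[["PV"]], tv[["TV"]])
    expect_lte(tv[["PS"]], tv[["TS"]])
    expect_lt(tv[["CD"]], tv[["WH"]])
  }
})

test_that("partial volume fraction is consistent with the conversion equation", {
  fx <- fixture("adult")
  frac <- fx$traits[["PV"]] / fx$traits[["TV"]]
  expect_gt(frac, 0.75)
  expect_lt(frac, 0.95)
})

test_that("cross-sections extract closed contours with a torso flag", {
  s <- cross_section(icosphere(0.5, 4), 0)
  expect_identical(length(s$loops), 1L)
  per <- bovimorph:::polyline_length(s$loops[[1]])
  expect_lt(abs(per / pi - 1), 0.005)

  # a station through the lower hind legs: leg contours separate from the
  # torso contour (the slanted cannon bones detach from the body there)
  fx <- fixture("adult")
  leg_x <- -0.62 * fx$params$torso_half_length - 0.12
  sc <- cross_section(fx$mesh, leg_x)
  expect_gte(length(sc$loops), 3L)
  expect_identical(length(sc$torso), 1L)
  ztop <- vapply(sc$loops, function(L) max(L[, 3]), numeric(1))
  expect_identical(which.max(ztop), sc$torso)

  expect_error(cross_section(fx$mesh, 100), "empty")
})

test_that("girth behaves like a taut tape", {
  s <- cross_section(icosphere(0.4, 4), 0)
  expect_lt(abs(as.numeric(girth(s)) / (2 * pi * 0.4) - 1), 0.002)

  # elliptic section vs quadrature oracle
  e <- ellipsoid_mesh(c(0.5, 0.35, 0.40), 4)
  g <- as.numeric(girth(cross_section(e, 0)))
  oracle <- 4 * integrate(function(t)
    sqrt((0.35 * sin(t))^2 + (0.40 * cos(t))^2), 0, pi / 2,
    rel.tol = 1e-10)$value
  expect_lt(abs(g / oracle - 1), 0.005)

  # ventral concavity: hull perimeter strictly below raw contour length
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  r <- 0.4 * (1 - 0.25 * exp(-((th - 4.7)^2) / 0.1))
  loop <- cbind(0, r * cos(th), r * sin(th))
  sec <- structure(list(station = 0, loops = list(loop), torso = 1L),
                   class = "cross_section")
  g2 <- girth(sec)
  expect_lt(as.numeric(g2), attr(g2, "raw_length"))
})

test_that("traits are symmetric under left-right mirroring", {
  fx <- fixture("adult")
  mm <- fx$mesh
  mm$vertices[, 2] <- -mm$vertices[, 2]
  mm$faces <- mm$faces[, c(1, 3, 2)]
  t1 <- suppressWarnings(measure_all(fx$mesh, fx$fp))
  t2 <- suppressWarnings(measure_all(mm, mirror_feature_points(fx$fp)))
  expect_equal(unclass(t1), unclass(t2), tolerance = 1e-9)
})

test_that("traits are invariant under rigid motion of mesh plus landmarks", {
  fx <- fixture("adult")
  R <- rotation_about("z", 0.6) %*% rotation_about("y", 0.15) %*%
    rotation_about("x", -0.25)
  tr <- c(2, -1, 0.5)
  m2 <- transform_mesh(fx$mesh, R, tr)
  fp2 <- transform_feature_points(fx$fp, R, tr)
  t1 <- suppressWarnings(measure_all(fx$mesh, fx$fp))
  t2 <- suppressWarnings(measure_all(m2, fp2))
  expect_equal(unclass(t1), unclass(t2), tolerance = 1e-9)
})

test_that("missing landmarks yield per-trait absence, not failure", {
  fx <- fixture("adult")
  fp <- fx$fp
  fp$landmarks <- fp$landmarks[rownames(fp$landmarks) != "withers", ,
                               drop = FALSE]
  expect_warning(tv <- measure_all(fx$mesh, fp), "WH")
  expect_true(is.na(tv[["WH"]]))
  expect_false(is.na(tv[["HW"]]))
  expect_false(is.na(tv[["TV"]]))
})

test_that("a synthetic fleet reproduces herd-scale trait means", {
  target <- c(TS = 7.202, TV = 0.7639, WH = 1.454, HW = 0.575,
              WB = 0.537, CD = 0.811, AC = 2.632)
  mn <- rowMeans(fixture("fleet16")$traits)[names(target)]
  for (tr in names(target))
    expect_lt(abs(mn[[tr]] / target[[tr]] - 1), 0.10)
})
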