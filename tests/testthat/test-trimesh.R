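test_that("divergence-theorem volume and area are exact on the cube", {
  m <- cube_mesh()
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 1)
  expect_equal(mesh_area(m), 6)

  # additivity over disjoint closed components
  m2 <- cube_mesh()
  m2$vertices <- m2$vertices + 5
  both <- trimesh(rbind(m$vertices, m2$vertices),
                  rbind(m$faces, m2$faces + nrow(m$vertices)))
  expect_equal(mesh_volume(both), 2)
})

test_that("sphere volume/area converge to closed forms with refinement", {
  exact_v <- 4 / 3 * pi * 0.125
  exact_a <- 4 * pi * 0.25
  err <- sapply(3:4, function(s) {
    m <- icosphere(0.5, s)
    c(v = abs(mesh_volume(m) / exact_v - 1),
      a = abs(mesh_area(m) / exact_a - 1))
  })
  expect_lt(err["v", 2], 0.005)
  expect_lt(err["a", 2], 0.005)
  # error decreases under refinement
  expect_lt(err["v", 2], err["v", 1])
  expect_lt(err["a", 2], err["a", 1])
})

test_that("volume and traits are invariant under rigid motion", {
  m <- icosphere(0.4, 3, center = c(0.2, -0.1, 0.5))
  R <- rotation_about("z", 0.7) %*% rotation_about("x", -0.3)
  m2 <- transform_mesh(m, R, c(1, 2, -3))
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-9)
  expect_equal(mesh_area(m2), mesh_area(m), tolerance = 1e-9)

  # uniform scaling: volume cubic, area quadratic
  m3 <- transform_mesh(m, scale = 3)
  expect_equal(mesh_volume(m3) / mesh_volume(m), 27, tolerance = 1e-9)
  expect_equal(mesh_area(m3) / mesh_area(m), 9, tolerance = 1e-9)
})

test_that("volume refuses non-watertight meshes with a defect report", {
  m <- cube_mesh()
  m$faces <- m$faces[-1, ]
  expect_false(is_watertight(m))
  expect_error(mesh_volume(m), "not watertight")
  expect_error(mesh_volume(m), "3")  # three open edges from one removed face
})

test_that("degenerate triangles contribute zero area", {
  m <- cube_mesh()
  m$faces <- rbind(m$faces, c(1, 1, 2))
  expect_equal(mesh_area(m), 6)
})

test_that("mesh and table IO round-trip", {
  m <- icosphere(0.3, 2)
  tmp <- tempfile(fileext = ".ply")
  write_ply(m, tmp, format = "binary")
  m2 <- read_ply(tmp)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)  # float32
  expect_identical(m2$faces, m$faces)
  write_ply(m, tmp, format = "ascii")
  m3 <- read_ply(tmp)
  expect_equal(m3$vertices, m$vertices, tolerance = 1e-6)

  tmp2 <- tempfile(fileext = ".obj")
  write_obj(m, tmp2)
  m4 <- read_obj(tmp2)
  expect_equal(m4$vertices, m$vertices, tolerance = 1e-6)
  expect_identical(m4$faces, m$faces)

  fx <- fixture("adult")
  tmp3 <- tempfile(fileext = ".csv")
  write_landmarks(fx$fp, tmp3)
  fp2 <- read_landmarks(tmp3)
  expect_equal(fp2$landmarks, fx$fp$landmarks)
  expect_equal(unname(fp2$stations), unname(fx$fp$stations))

  tab <- measurement_table("a", 1, 1:3, "WH", c(1.4, 1.41, 1.39), "m")
  tmp4 <- tempfile(fileext = ".csv")
  write_measurements(tab, tmp4)
  expect_equal(as.data.frame(read_measurements(tmp4)), as.data.frame(tab))
})

test_that("depth maps and rigs round-trip through PGM and YAML", {
  cam <- camera_model(fx = 300, width = 64, height = 48)
  z <- matrix(runif(64 * 48, 0.5, 3), 48, 64)
  z[1, 1] <- NA
  d <- depth_map(z, cam)
  tmp <- tempfile(fileext = ".pgm")
  write_depth_pgm(d, tmp)
  z2 <- read_depth_pgm(tmp)
  expect_equal(dim(z2), dim(z))
  expect_true(is.na(z2[1, 1]))
  expect_equal(z2[-1], z[-1], tolerance = 6e-4)  # mm rounding

  rig <- default_rig(width = 64)
  tmp2 <- tempfile(fileext = ".yaml")
  write_rig_yaml(rig, tmp2)
  rig2 <- read_rig_yaml(tmp2)
  expect_equal(length(rig2$cameras), 15)
  for (i in c(1, 8, 15)) {
    expect_equal(rig2$cameras[[i]]$rotation, rig$cameras[[i]]$rotation,
                 tolerance = 1e-9)
    expect_equal(rig2$cameras[[i]]$translation,
                 rig$cameras[[i]]$translation, tolerance = 1e-12)
  }
})
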