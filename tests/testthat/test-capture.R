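test_that("camera model validates intrinsics and pose", {
  expect_error(camera_model(fx = -1), "positive")
  expect_error(camera_model(fx = 300, rotation = diag(c(1, 1, 2))),
               "orthonormal")
  expect_error(camera_model(fx = 300, quant_step = -0.001), "non-negative")
  cam <- look_at_camera(c(0, 0, 2), c(0, 0, 0), fx = 300, width = 100,
                        height = 100, up = c(1, 0, 0))
  expect_equal(abs(det(cam$rotation)), 1, tolerance = 1e-12)
})

test_that("a fronto-parallel plane renders at constant depth", {
  cam <- camera_model(fx = 200, width = 120, height = 90)
  plane <- trimesh(rbind(c(-5, -5, 2), c(5, -5, 2), c(5, 5, 2),
                         c(-5, 5, 2)),
                   rbind(c(1, 2, 3), c(1, 3, 4)))
  d <- render_depth(plane, cam)
  expect_true(all(is.finite(d$depth)))
  expect_equal(max(abs(d$depth - 2)), 0, tolerance = 1e-12)
})

test_that("a unit sphere on the optical axis renders center depth D - 1", {
  # principal point chosen on a pixel center; sphere rotated so a vertex
  # lies exactly on the axis, making the expected depth exact
  cam <- camera_model(fx = 300, cx = 60.5, cy = 40.5, width = 120,
                      height = 80)
  sp <- axis_aligned_sphere(1, 3, center = c(0, 0, 3))
  d <- render_depth(sp, cam)
  expect_equal(d$depth[41, 61], 2, tolerance = 1e-6)
})

test_that("a camera inside the mesh yields an all-invalid map with warning", {
  cam <- camera_model(fx = 100, width = 20, height = 20)
  sp <- icosphere(2, 3)
  expect_warning(d <- render_depth(sp, cam), "inside")
  expect_true(all(is.na(d$depth)))
})

test_that("depth quantization rounds to the step and is unbiased in RMS", {
  cam <- camera_model(fx = 100, width = 2, height = 1)
  d <- depth_map(matrix(c(1.004, 1.006), 1, 2), cam)
  expect_identical(quantize_depth(d, 0)$depth, d$depth)
  expect_equal(as.numeric(quantize_depth(d, 0.01)$depth), c(1.00, 1.01))

  set.seed(5)
  z <- matrix(runif(40000, 1, 2), 200, 200)
  q <- quantize_depth(depth_map(z, cam), 0.01)
  rms <- sqrt(mean((q$depth - z)^2))
  expect_lt(abs(rms / (0.01 / sqrt(12)) - 1), 0.02)
})

test_that("bilateral smoothing flattens the staircase but keeps edges", {
  cam <- camera_model(fx = 100, width = 160, height = 120)
  const <- depth_map(matrix(1.5, 120, 160), cam)
  expect_equal(smooth_depth(const)$depth, const$depth, tolerance = 1e-12)

  true_z <- outer(seq(1.5, 1.7, length.out = 120),
                  seq(0, 0.1, length.out = 160), "+")
  q <- quantize_depth(depth_map(true_z, cam), 0.002)
  s <- smooth_depth(q, spatial_radius = 4, range_sigma = 0.006)
  inner <- function(m) m[10:110, 10:150]
  rms_q <- sqrt(mean((inner(q$depth) - inner(true_z))^2))
  rms_s <- sqrt(mean((inner(s$depth) - inner(true_z))^2))
  expect_gte(rms_q / rms_s, 3)

  # a 0.1 m step edge moves by less than 1 mm under range_sigma 2 mm
  edge <- matrix(1.5, 100, 100)
  edge[, 51:100] <- 1.6
  se <- smooth_depth(depth_map(edge, cam), 4, 0.002)
  expect_lt(max(abs(se$depth - edge)), 0.001)

  # validity mask untouched
  holed <- depth_map(rbind(c(1.5, NA), c(1.5, 1.5)),
                     camera_model(fx = 10, width = 2, height = 2))
  expect_identical(is.na(smooth_depth(holed, 1)$depth), is.na(holed$depth))
})

test_that("backprojection inverts the pinhole model and estimates normals", {
  cam <- camera_model(fx = 250, cx = 40.5, cy = 30.5, width = 80,
                      height = 60)
  d <- depth_map(matrix(1.7, 60, 80), cam)
  pc <- backproject(d)
  # principal-point pixel lies on the optical axis at the map depth
  onaxis <- pc$points[abs(pc$points[, 1]) < 1e-9 &
                      abs(pc$points[, 2]) < 1e-9, , drop = FALSE]
  expect_identical(nrow(onaxis), 1L)
  expect_equal(sqrt(sum(onaxis^2)), 1.7, tolerance = 1e-12)

  # tilted plane: least-squares plane normal within 1 degree of truth
  n_true <- c(0.3, -0.2, 1)
  n_true <- n_true / sqrt(sum(n_true^2))
  u <- matrix(rep(0:79, each = 60), 60, 80)
  v <- matrix(rep(0:59, 80), 60, 80)
  # plane n . p = c with p = z*((u-cx)/fx, (v-cy)/fy, 1)
  zz <- 1.5 / (n_true[1] * (u + 0.5 - cam$cx) / cam$fx +
               n_true[2] * (v + 0.5 - cam$cy) / cam$fy + n_true[3])
  pcl <- backproject(depth_map(zz, cam))
  cen <- scale(pcl$points, scale = FALSE)
  nfit <- svd(cen)$v[, 3]
  ang <- acos(abs(sum(nfit * n_true))) * 180 / pi
  expect_lt(ang, 1)
  # estimated per-point normals are camera-facing
  expect_true(all(rowSums(pcl$normals * pcl$points) <= 0))
})

test_that("pose application and inversion round-trip to 1e-9", {
  R <- rotation_about("z", 0.8) %*% rotation_about("x", 0.2)
  p <- list(rotation = R, translation = c(0.4, -0.2, 1.1))
  rt <- compose_pose(invert_pose(p), p)
  expect_equal(rt$rotation, diag(3), tolerance = 1e-9)
  expect_equal(rt$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("rendered points back-project onto the source surface", {
  fx <- fixture("adult")
  cam <- look_at_camera(c(0, 1.8, 1.0), c(0, 0, 0.8), fx = 180,
                        width = 212, height = 120)
  d <- quantize_depth(render_depth(fx$mesh, cam), 0.002)
  pc <- backproject(d)
  dist <- bovimorph:::.point_mesh_distance(fx$mesh$vertices, fx$mesh$faces,
                                           pc$points)
  expect_lt(max(dist), 0.002 + 1e-6)
})

test_that("pair calibration recovers rigid poses", {
  set.seed(3)
  corners <- matrix(runif(120, -0.3, 0.3), 40, 3)
  expect_equal(calibrate_pair(corners, corners)$rotation, diag(3),
               tolerance = 1e-12)

  R <- rotation_about("z", pi / 6)
  tt <- c(0.5, 0, 0)
  obs_a <- sweep(corners %*% t(R), 2, tt, "+")
  cal <- calibrate_pair(obs_a, corners)
  expect_equal(cal$rotation, R, tolerance = 1e-6)
  expect_equal(cal$translation, tt, tolerance = 1e-6)

  # 1 mm corner noise: translation error 95th percentile below 2 mm
  terr <- numeric(100)
  for (i in 1:100) {
    noisy <- obs_a + matrix(rnorm(120, 0, 0.001), 40, 3)
    terr[i] <- sqrt(sum((calibrate_pair(noisy, corners)$translation -
                         tt)^2))
  }
  expect_lt(quantile(terr, 0.95), 0.002)

  expect_error(calibrate_pair(cbind(1:9, 0, 0), cbind(1:9, 0, 0)),
               "collinear")
})

test_that("chained pairwise calibrations close around the rig", {
  rig <- default_rig(width = 32)
  set.seed(9)
  board_w <- matrix(runif(90, -0.4, 0.4), 30, 3)
  to_cam <- function(cam, pw)
    sweep(pw, 2, cam$translation, "-") %*% cam$rotation
  chain <- identity_pose()
  n <- length(rig$cameras)
  for (i in seq_len(n)) {
    a <- rig$cameras[[i]]
    b <- rig$cameras[[if (i == n) 1 else i + 1]]
    chain <- compose_pose(chain,
                          calibrate_pair(to_cam(a, board_w),
                                         to_cam(b, board_w)))
  }
  expect_equal(chain$rotation, diag(3), tolerance = 15 * 1e-6)
  expect_equal(chain$translation, c(0, 0, 0), tolerance = 15 * 1e-6)
})

test_that("merging transforms clouds into one frame and de-duplicates", {
  set.seed(4)
  dirs <- matrix(rnorm(3000), 1000, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cl <- point_cloud(dirs * 0.5, dirs)
  m1 <- merge_clouds(list(cl), list(identity_pose()), dedup_radius = 0)
  expect_equal(m1$points, cl$points)

  expect_error(merge_clouds(list(cl, cl), list(identity_pose())),
               "mismatch")

  # two rendered half-views of a sphere fuse onto the analytic surface
  sp <- icosphere(0.5, 5, center = c(0, 0, 1.5))
  cams <- list(
    look_at_camera(c(0, 2.2, 1.5), c(0, 0, 1.5), fx = 220, width = 160,
                   height = 160),
    look_at_camera(c(0, -2.2, 1.5), c(0, 0, 1.5), fx = 220, width = 160,
                   height = 160))
  clouds <- lapply(seq_along(cams), function(i)
    backproject(quantize_depth(render_depth(sp, cams[[i]]), 0.001),
                camera_index = i))
  merged <- merge_clouds(clouds, dedup_radius = 0.002)
  r_err <- abs(sqrt(rowSums(sweep(merged$points, 2,
                                  c(0, 0, 1.5))^2)) - 0.5)
  expect_lt(max(r_err), 0.001 + 0.003)  # quantization + facet tolerance
})

test_that("the default rig covers the whole body surface when merged", {
  p <- cow_params(mesh_resolution = 3)
  m <- make_cow_mesh(p)
  rig <- default_rig(quant_step = 0)
  clouds <- lapply(seq_along(rig$cameras), function(i)
    backproject(render_depth(m, rig$cameras[[i]]), camera_index = i))
  merged <- merge_clouds(clouds, dedup_radius = 0.004)
  fc <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
         m$vertices[m$faces[, 3], ]) / 3
  dsrc <- bovimorph:::.nearest_point_distance(merged$points, fc)
  expect_gte(mean(dsrc < 0.01), 0.99)
})

test_that("surface reconstruction meets the sphere fidelity contract", {
  set.seed(6)
  n <- 50000
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- dirs * 0.5 + dirs * rnorm(n, 0, 0.001)
  cl <- point_cloud(pts, dirs)
  m <- reconstruct_surface(cl, voxel = 0.01)
  expect_true(is_watertight(m))
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * 0.5^3) - 1), 0.02)

  # a hemisphere cannot close a surface: structured failure, never a
  # silently wrong mesh
  top <- dirs[, 3] > 0
  expect_error(reconstruct_surface(point_cloud(pts[top, ], dirs[top, ]),
                                   voxel = 0.01),
               class = "reconstruction_error")
})

test_that("finer quantization never worsens end-to-end volume (median)", {
  sp <- icosphere(0.5, 4, center = c(0, 0, 1.2))
  v_true <- mesh_volume(sp)
  cams <- lapply(seq(0, 2 * pi, length.out = 7)[-7], function(a)
    look_at_camera(c(2 * cos(a), 2 * sin(a), 1.2 + 0.6 * sin(3 * a)),
                   c(0, 0, 1.2), fx = 200, width = 150, height = 150,
                   noise_sd = 0.001))
  run_once <- function(step, seed) {
    set.seed(seed)
    clouds <- lapply(seq_along(cams), function(i)
      backproject(quantize_depth(render_depth(sp, cams[[i]]), step),
                  camera_index = i))
    rec <- reconstruct_surface(merge_clouds(clouds, dedup_radius = 0.003),
                               voxel = 0.0125, coverage_max_dist = 0.08)
    abs(mesh_volume(rec) / v_true - 1)
  }
  steps <- c(0.012, 0.004, 0)
  med <- sapply(steps, function(s)
    median(sapply(1:3, function(seed) run_once(s, seed))))
  expect_true(all(diff(med) <= 1e-3))  # non-increasing within tolerance
})
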