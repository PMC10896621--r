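test_that("identical paired tables yield zero differences", {
  pm <- paired_measurements(rep(sprintf("c%d", 1:5), 2),
                            rep(c("WH", "TV"), each = 5),
                            rep(c(1.45, 0.74), each = 5),
                            rep(c(1.45, 0.74), each = 5))
  tab <- paired_differences(pm)
  expect_equal(tab$abs_difference, c(0, 0))
  expect_equal(tab$rel_difference_percent, c(0, 0))
})

test_that("difference table reproduces the printed device comparison", {
  pm <- paired_measurements(c("a", "b", "a", "b"),
                            c("TV", "TV", "TS", "TS"),
                            c(739.8, 739.8, 7.481, 7.481),
                            c(738.6, 738.6, 6.881, 6.881))
  tab <- paired_differences(pm)
  tv <- tab[tab$trait == "TV", ]
  expect_equal(tv$abs_difference, 1.2)
  expect_lt(tv$rel_difference_percent, 0.2)
  ts <- tab[tab$trait == "TS", ]
  expect_equal(ts$abs_difference, 0.6)
  expect_equal(ts$rel_difference_percent, 8.02, tolerance = 0.001)
})

test_that("device regression is exact on noise-free pairs and flags sign", {
  pm <- paired_measurements(sprintf("c%d", 1:5), "WH",
                            c(1.3, 1.4, 1.5, 1.6, 1.7),
                            c(1.3, 1.4, 1.5, 1.6, 1.7))
  r <- regress_devices(pm, "WH")
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  anti <- paired_measurements(sprintf("c%d", 1:5), "WH",
                              c(1.3, 1.4, 1.5, 1.6, 1.7),
                              c(1.7, 1.6, 1.5, 1.4, 1.3))
  expect_warning(ra <- regress_devices(anti, "WH"), "negative")
  expect_true(ra$negative_slope)
  expect_lt(ra$slope, 0)

  flat <- paired_measurements(sprintf("c%d", 1:4), "WH", rep(1.5, 4),
                              c(1.4, 1.5, 1.6, 1.5))
  expect_error(regress_devices(flat, "WH"), "variance")
})

test_that("a known device slope is recovered from noisy synthetic pairs", {
  set.seed(17)
  slopes <- numeric(100)
  for (s in 1:100) {
    ref <- runif(200, 0.5, 0.65)
    test <- 0.97 * ref + rnorm(200, 0, 0.01 * 0.575)
    pm <- paired_measurements(sprintf("c%d", 1:200), "HW", ref, test)
    slopes[s] <- regress_devices(pm, "HW")$slope
  }
  expect_lt(abs(mean(slopes) - 0.97), 0.01)
})

test_that("swapping reference and test negates differences, inverts slope", {
  set.seed(23)
  ref <- runif(10, 1.3, 1.6)
  test <- 0.96 * ref + 0.02
  pm <- paired_measurements(sprintf("c%d", 1:10), "WH", ref, test)
  pm_sw <- paired_measurements(sprintf("c%d", 1:10), "WH", test, ref)
  d1 <- paired_differences(pm)
  d2 <- paired_differences(pm_sw)
  expect_equal(d2$abs_difference, d1$abs_difference, tolerance = 1e-12)
  s1 <- regress_devices(pm, "WH")$slope
  s2 <- regress_devices(pm_sw, "WH")$slope
  expect_equal(s2, 1 / s1, tolerance = 1e-9)
})

test_that("unpaired records are dropped with an enumeration", {
  expect_warning(pm <- paired_measurements(c("a", "b", "c"), "TV",
                                           c(0.7, NA, 0.75),
                                           c(0.71, 0.72, 0.74)),
                 "unpaired")
  expect_identical(attr(pm, "dropped"), "b")
  expect_identical(nrow(pm), 2L)
})

test_that("body-weight validation regression behaves at the extremes", {
  pred <- c(450, 480, 510, 540)
  r <- validate_bw(pred, pred)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$rmse, 0)
  expect_error(validate_bw(pred, pred[1:3]), "mismatch")
  expect_error(validate_bw(rep(500, 4), c(450, 480, 510, 540)),
               "variance")
})

test_that("the demo pipeline runs quickly and is byte-deterministic", {
  out1 <- file.path(tempdir(), "demo_a")
  out2 <- file.path(tempdir(), "demo_b")
  t0 <- Sys.time()
  res <- run_pipeline(demo_config(seed = 3, output_dir = out1))
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 120)
  expect_true(all(file.exists(res$paths)))
  expect_true(all(res$table1$verdict_below_4pct_repeatability))

  run_pipeline(demo_config(seed = 3, output_dir = out2))
  for (f in c("table1.csv", "table3.csv", "bw_validation.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})
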