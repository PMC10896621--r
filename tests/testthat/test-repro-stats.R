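test_that("ANOVA-residual sigma matches hand and brute-force oracles", {
  tab <- measurement_table(rep(c("a", "b"), each = 2), 1, c(1, 2, 1, 2),
                           "PV", c(1, 3, 5, 7), "m3")
  r <- residual_sd(tab, "PV")
  expect_equal(r$sigma, sqrt(4 / 2))
  expect_equal(r$df, 2)

  # identical values
  tab0 <- measurement_table("a", 1, 1:4, "WH", rep(1.4, 4), "m")
  expect_equal(residual_sd(tab0, "WH")$sigma, 0)

  # property: equals pooled within-group SD on random unbalanced tables
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    reps <- sample(2:6, k, replace = TRUE)
    subj <- rep(sprintf("s%d", seq_len(k)), reps)
    vals <- rnorm(sum(reps), mean = 100, sd = 3) +
      rep(rnorm(k, 0, 10), reps)
    tb <- measurement_table(subj, 1, unlist(lapply(reps, seq_len)),
                            "x", vals, "u")
    expect_equal(residual_sd(tb, "x")$sigma,
                 pooled_sd_oracle(vals, subj), tolerance = 1e-12)
  }

  expect_error(residual_sd(measurement_table("a", 1, 1, "x", 1, "u"), "x"),
               "degree")
})

test_that("coefficient of variation matches the printed withers-height row", {
  expect_equal(cv_percent(1, 100), 1)
  expect_equal(cv_percent(0, 5), 0)
  # sigma and mean as printed give a CV that rounds to the table value
  expect_equal(round(cv_percent(0.0186, 1.454), 1), 1.3)
  expect_lt(abs(cv_percent(0.0186, 1.454) - 1.279), 0.001)
  expect_error(cv_percent(1, 0), "positive")
})

test_that("errors from CVs reproduce the worked illustrations", {
  expect_equal(round(error_from_cv(1.29, 1.45), 3), 0.019)
  expect_equal(round(error_from_cv(1.77, 7.20), 2), 0.13)
  expect_equal(error_from_cv(0, 3), 0)
})

test_that("the 95% limit is the Gaussian two-determination quantile", {
  expect_equal(limit_95(0), 0)
  expect_equal(limit_95(1), qnorm(0.975) * sqrt(2))
  expect_equal(limit_95(1), 2.7718, tolerance = 1e-4)

  # Monte-Carlo coverage of |x1 - x2| <= r
  set.seed(123)
  n <- 2e5
  sigma <- 9
  r <- limit_95(sigma)
  cover <- mean(abs(rnorm(n, 764, sigma) - rnorm(n, 764, sigma)) <= r)
  expect_lt(abs(cover - 0.95), 0.004)
})

test_that("sigma, error and limit are scale-equivariant; CV is not", {
  tab <- measurement_table(rep(c("a", "b", "c"), each = 4), 1,
                           rep(1:4, 3), "x",
                           rnorm(12, 50, 2) + rep(c(0, 5, -4), each = 4),
                           "u")
  a1 <- assess(tab)
  tab2 <- tab
  tab2$value <- tab2$value * 7
  a2 <- assess(tab2)
  expect_equal(a2$sigma / a1$sigma, 7, tolerance = 1e-12)
  expect_equal(a2$error / a1$error, 7, tolerance = 1e-12)
  expect_equal(a2$limit_r / a1$limit_r, 7, tolerance = 1e-12)
  expect_equal(a2$cv_percent, a1$cv_percent, tolerance = 1e-12)
})

test_that("the 4% verdict flags an injected large within-subject noise", {
  set.seed(11)
  good <- rep(rnorm(8, 764, 50), each = 5) + rnorm(40, 0, 9)
  bad <- rep(rnorm(8, 764, 50), each = 5) + rnorm(40, 0, 0.08 * 764)
  tab <- measurement_table(rep(sprintf("c%d", 1:8), each = 5), 1,
                           rep(1:5, 8), rep(c("TV", "BAD"), each = 40),
                           c(good, bad), "L")
  a <- assess(tab)
  expect_true(a$verdict_below_4pct[a$trait == "TV"])
  expect_false(a$verdict_below_4pct[a$trait == "BAD"])
  expect_equal(a$error, a$sigma)
  expect_equal(a$limit_r, limit_95(a$sigma))
})

test_that("injected CV is recovered without material bias at 8 x 5", {
  cvs <- numeric(200)
  true_cv <- 2.5
  for (s in seq_len(200)) {
    set.seed(s)
    vals <- rep(rnorm(8, 764, 60), each = 5) +
      rnorm(40, 0, true_cv / 100 * 764)
    tab <- measurement_table(rep(sprintf("c%d", 1:8), each = 5), 1,
                             rep(1:5, 8), "TV", vals, "L")
    r <- residual_sd(tab, "TV")
    cvs[s] <- cv_percent(r$sigma, r$mean)
  }
  expect_lt(abs(mean(cvs) / true_cv - 1), 0.03)
})

test_that("reproducibility CV dominates repeatability CV on matched designs", {
  # matched mesh-based designs at the default noise calibration
  pars <- fleet_params(2, "adult", size_cv = 0.02, seed = 71,
                       mesh_resolution = 1.2)
  mean_cvs <- function(st) {
    a <- assess(measure_study(st))
    mean(a$cv_percent)
  }
  n_seeds <- 100
  cv_rp <- cv_ri <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    rp <- generate_study(study_design("repeatability", 2, 1, 3,
                                      noise_model(seed = 1000 + s)), pars)
    ri <- generate_study(study_design("reproducibility", 2, 2, 3,
                                      noise_model(seed = 1000 + s)), pars)
    cv_rp[s] <- mean_cvs(rp)
    cv_ri[s] <- mean_cvs(ri)
  }
  expect_gt(mean(cv_ri), mean(cv_rp))
  # all simulated CVs stay below the 4% quality threshold
  expect_lt(max(cv_ri), 4)
})
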