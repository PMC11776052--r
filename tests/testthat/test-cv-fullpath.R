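test_that("switching pair is complementary, intersecting at cv0, and logistic", {
  x <- seq(-2, 3, length.out = 5001)
  sw <- switching_pair(x, cv0 = 0.95, alpha = 20)
  expect_equal(sw$s1 + sw$s2, rep(1, length(x)))
  expect_equal(switching_pair(0.95)$s1, 0.5)
  expect_true(all(diff(sw$s1) <= 0))
  expect_true(all(diff(sw$s2) >= 0))
  # strictly monotone where the logistic is not saturated in double precision
  xc <- seq(0.3, 1.6, length.out = 2001)
  swc <- switching_pair(xc, cv0 = 0.95, alpha = 20)
  expect_true(all(diff(swc$s1) < 0))
  expect_true(all(diff(swc$s2) > 0))
  # limits
  expect_equal(switching_pair(-50)$s1, 1)
  expect_equal(switching_pair(50)$s2, 1)
  # frozen value of the closed form at x = 0.90: 1 / (1 + exp(-1))
  expect_equal(switching_pair(0.90, cv0 = 0.95, alpha = 20)$s1,
               0.731058578630005, tolerance = 1e-12)
  expect_error(switching_pair(0, alpha = -1), "alpha")
})

test_that("cylinder soft count matches the rational membership", {
  # every stacked lipid contributes its T and TT bead to the count
  on_axis <- stacked_lipids(matrix(0, 3, 2))
  expect_equal(cylinder_soft_count(on_axis), 6, tolerance = 1e-9)

  far <- stacked_lipids(matrix(c(5, 5, -5, 5, 5, -5), 3, 2, byrow = TRUE))
  expect_lt(cylinder_soft_count(far), 1e-3)

  # single site exactly at rho = R_cyl: w -> n/m = 1/2 per tail bead
  at_r <- stacked_lipids(matrix(c(1.2, 0), 1, 2))
  expect_equal(cylinder_soft_count(at_r), 2 * 0.5, tolerance = 1e-9)

  # general exponents: limit still n/m
  p <- cv_params(boundary_exponents = c(4L, 10L))
  expect_equal(cylinder_soft_count(at_r, p), 2 * 4 / 10, tolerance = 1e-6)

  water_only <- particle_configuration(matrix(1, 1, 3), "water",
                                       NA_integer_, c(5, 5, 5))
  expect_error(cylinder_soft_count(water_only), "tail")
})

test_that("defect coordinate is an affine readout of the soft count", {
  expect_equal(cv_cyl(10, 10), 0)
  expect_equal(cv_cyl(0, 10), 1)
  expect_equal(cv_cyl(11, 10), -0.1)
  expect_error(cv_cyl(1, 0), "cv_eq")
})

test_that("calibration averages frame counts and is self-consistent", {
  f1 <- stacked_lipids(matrix(0, 5, 2))          # d = 10
  f2 <- stacked_lipids(matrix(0, 6, 2))          # d = 12
  p <- calibrate_cv_eq(list(f1, f2))
  expect_equal(p$cv_eq, 11, tolerance = 1e-9)
  expect_equal(attr(p, "n_frames"), 2L)

  p1 <- calibrate_cv_eq(f1)
  expect_equal(p1$cv_eq, cylinder_soft_count(f1))
  expect_equal(cv_cyl(cylinder_soft_count(f1), p1$cv_eq), 0)

  flat <- flat_fixture()
  pf <- calibrated_params()
  expect_equal(cv_cyl(cylinder_soft_count(flat), pf$cv_eq), 0,
               tolerance = 1e-12)
  expect_error(calibrate_cv_eq(list()), "at least one")
})

test_that("soft minimum underestimates and converges to the true minimum", {
  expect_equal(soft_min(1.0, beta = 50), 1.0)
  expect_lte(soft_min(c(1, 2), beta = 200), 1)
  expect_equal(soft_min(c(1, 2), beta = 200), 1, tolerance = 0.01)

  with_seed(42, {
    for (i in 1:50) {
      d <- runif(sample(2:30, 1), 0.2, 5)
      r200 <- soft_min(d, beta = 200)
      expect_lte(r200, min(d) * (1 + 1e-12))   # underestimate, up to rounding
      expect_gt(r200, 0.99 * min(d))
      # monotone convergence in beta
      betas <- c(25, 50, 100, 200, 400)
      rs <- vapply(betas, function(b) soft_min(d, beta = b), numeric(1))
      expect_true(all(diff(rs) > -1e-12))
      # a particle farther than all others barely changes the result
      expect_lt(abs(soft_min(c(d, max(d) + 3), beta = 200) - r200), 1e-6)
    }
  })
  expect_error(soft_min(numeric(0)), "empty")
})

test_that("soft-min radius of a configuration tracks the nearest tail", {
  # one near site, one much farther: effectively a one-term sum
  cfg <- stacked_lipids(matrix(c(1, 0, 4.5, 0), 2, 2, byrow = TRUE))
  # two coincident near beads contribute log(2)/beta relative shortfall
  expect_equal(soft_min_radius(cfg, cv_params(softmin_beta = 200)), 1,
               tolerance = 5e-3)
  expect_lte(soft_min_radius(cfg, cv_params(softmin_beta = 200)), 1)
})

test_that("joint CV blends defect and radius coordinates", {
  params <- calibrated_params()
  flat <- flat_fixture()
  v <- fullpath_cv(flat, params)
  expect_lt(abs(v$value), 0.05)
  expect_equal(v$s1 + v$s2, 1)
  expect_equal(v$value, v$s1 * v$cv_cyl + v$s2 * v$cv_radius,
               tolerance = 1e-12)

  pore <- pore_fixture(1.5)
  vp <- fullpath_cv(pore, params)
  expect_equal(vp$value, 1.5, tolerance = 0.1 * 1.5)
  expect_error(fullpath_cv(flat, cv_params()), "calibrated")
})

test_that("defect coordinate decreases when a tail moves into the cylinder", {
  params <- calibrated_params()
  pore <- pore_fixture(1.5)
  v0 <- fullpath_cv(pore, params)
  moved <- pore
  i <- which(moved$roles == "tail")[1]
  moved$positions[i, 1:2] <- moved$box[1:2] / 2    # onto the axis
  v1 <- fullpath_cv(moved, params)
  expect_lt(v1$cv_cyl, v0$cv_cyl)
  expect_lt(v1$cv_radius, v0$cv_radius)
})

test_that("analytic gradient matches finite differences on all fixture classes", {
  params <- calibrated_params(n_lipids = 32)
  h <- 1e-5
  check_grad <- function(cfg, n_probe = 8) {
    v <- fullpath_cv(cfg, params)
    idx <- with_seed(7, sample(n_particles(cfg), n_probe))
    for (i in idx) for (k in 1:3) {
      cp <- cfg; cp$positions[i, k] <- cp$positions[i, k] + h
      cm <- cfg; cm$positions[i, k] <- cm$positions[i, k] - h
      fd <- (fullpath_cv(cp, params, gradient = FALSE)$value -
             fullpath_cv(cm, params, gradient = FALSE)$value) / (2 * h)
      expect_lt(abs(fd - v$gradient[i, k]), 1e-5)
    }
    # water and head beads carry zero gradient
    inert <- cfg$roles %in% c("head", "water")
    expect_true(all(v$gradient[inert, ] == 0))
  }
  check_grad(flat_fixture(32, seed = 2))
  check_grad(pore_fixture(1.2, n_lipids = 128))
  check_grad(build_stripe(geometry_spec(n_lipids = 60, stripe = TRUE,
                                        water_density = 0)))
})

test_that("CV series over frames writes COLVAR-compatible records", {
  params <- calibrated_params(n_lipids = 32)
  frames <- list(flat_fixture(32, seed = 2), flat_fixture(32, seed = 2))
  df <- fullpath_cv_series(frames, params, times = c(0, 10))
  expect_named(df, c("time", "cv", "cv_cyl", "cv_radius", "s1", "s2"))
  expect_equal(nrow(df), 2L)
  f <- withr::local_tempfile(fileext = ".colvar")
  write_series(df, f)
  back <- read_series(f)
  expect_equal(back$cv, df$cv, tolerance = 1e-9)
})

test_that("cv_params validates its domain", {
  expect_error(cv_params(cv0 = 0.4), "cv0")
  expect_error(cv_params(cv0 = 1), "cv0")
  expect_error(cv_params(alpha = 0), "alpha")
  expect_error(cv_params(r_cyl = -1), "r_cyl")
  expect_error(cv_params(softmin_beta = 0), "softmin_beta")
  expect_error(cv_params(boundary_exponents = c(12, 6)), "increasing")
})
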