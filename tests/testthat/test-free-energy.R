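test_that("window centers are laid out inclusively and guarded", {
  centers <- make_window_centers(-0.100, 2.175, spacing = 0.035)
  expect_equal(length(centers), 66L)
  expect_equal(centers[1], -0.1)
  expect_equal(centers[66], 2.175)

  c21 <- make_window_centers(6.0, 6.6, n = 21)
  expect_equal(length(c21), 21L)
  expect_equal(unique(round(diff(c21), 10)), 0.03)

  expect_error(make_window_centers(0, 1, spacing = 2), "exceeds")
  expect_error(make_window_centers(0, 1, spacing = 0.3), "evenly divide")
  expect_error(make_window_centers(1, 0, spacing = 0.1), "exceed")
  expect_error(make_window_centers(0, 1), "exactly one")
})

test_that("window seeding picks nearest frames with earliest tie-break", {
  frames <- as.list(1:5)
  cv <- c(0.0, 0.5, 1.0, 1.5, 2.0)
  expect_equal(seed_windows(frames, cv, c(0.5, 1.4)), c(2L, 4L))
  expect_error(seed_windows(frames, cv, 2.5), "outside")
  # equidistant: earliest frame wins
  expect_equal(seed_windows(as.list(1:2), c(0, 2), 1), 1L)
})

test_that("WHAM recovers a flat profile from unbiased-like sampling", {
  w <- with_seed(4, umbrella_window(0.5, 1e-8, runif(50000)))
  prof <- suppressWarnings(wham_solve(list(w), n_bins = 50))
  g <- prof$G[prof$sampled]
  expect_lt(max(abs(g - mean(g))), 0.3)
  expect_equal(min(prof$G[prof$sampled]), 0)
})

test_that("WHAM recovers a linear potential from two overlapping windows", {
  # the recovered tilt of a harmonic window has standard error
  # kappa * sigma / sqrt(n), so a soft bias and ample samples are needed
  # for a percent-level slope check
  slope <- 5
  g <- function(x) slope * x
  windows <- with_seed(5, lapply(c(0.35, 0.65), function(ct)
    umbrella_window(ct, 200, sample_biased_boltzmann(g, ct, 200, 1e5,
                                                     lo = -0.5, hi = 1.5))))
  prof <- wham_solve(windows, n_bins = 80)
  keep <- prof$sampled & prof$grid >= 0.2 & prof$grid <= 0.8
  fit <- lm(prof$G[keep] ~ prof$grid[keep])
  expect_equal(unname(coef(fit)[2]), slope, tolerance = 0.02)
})

test_that("WHAM recovers the double-well oracle and is order-invariant", {
  g <- double_well()
  windows <- oracle_windows(n = 2000, seed = 2)
  prof <- wham_solve(windows)
  expect_lt(profile_rms(prof, g), 0.5)
  # window order must not matter
  prof2 <- wham_solve(rev(windows), edges = prof$meta$edges)
  ok <- prof$sampled & prof2$sampled
  expect_lt(max(abs(prof$G[ok] - prof2$G[ok])), 1e-6)
  # profile minimum is exactly zero at the reference bin
  expect_equal(min(prof$G[prof$sampled]), 0)
  expect_equal(prof$G[prof$reference], 0)
})

test_that("WHAM rejects mixed temperatures and warns on poor overlap", {
  w1 <- umbrella_window(0, 100, rnorm(100), temperature = 310)
  w2 <- umbrella_window(1, 100, rnorm(100) + 1, temperature = 300)
  expect_error(wham_solve(list(w1, w2)), "mixed-temperature")

  far <- with_seed(6, list(
    umbrella_window(0, 5000, rnorm(1000, 0, 0.02)),
    umbrella_window(1, 5000, rnorm(1000, 1, 0.02))))
  expect_warning(try(wham_solve(far, n_bins = 100), silent = TRUE),
                 "histogram weight")
})

test_that("quadratic fits are exact on noiseless profiles and range-limited", {
  grid <- seq(0, 1, by = 0.02)
  prof <- free_energy_profile(grid, 3 * grid^2)
  fit <- fit_quadratic(prof)
  expect_equal(fit$k, 3, tolerance = 1e-12)
  expect_equal(fit$c, 0, tolerance = 1e-12)

  prof2 <- free_energy_profile(grid, 3 * grid^2 + 1)
  fit2 <- fit_quadratic(prof2)
  expect_equal(fit2$k, 3, tolerance = 1e-12)
  # the profile container shifts G so min = 0; the intercept moves with it
  expect_equal(fit2$c, 0, tolerance = 1e-12)

  # an outlier beyond the fit range leaves k untouched
  g3 <- 3 * grid^2
  g3[grid > 0.55 & grid < 0.65] <- 10
  fit3 <- fit_quadratic(free_energy_profile(grid, g3))
  expect_equal(fit3$k, 3, tolerance = 1e-12)
  expect_error(fit_quadratic(free_energy_profile(c(0.8, 0.9, 1),
                                                 c(0, 1, 2))),
               "at least 3")
})

test_that("line-tension profile fits invert their construction exactly", {
  grid <- seq(1.2, 2.4, by = 0.02)
  gamma0 <- 2
  prof <- free_energy_profile(grid, 2 * pi * gamma0 * grid)
  fit <- fit_line_tension_profile(prof, mode = "fullpath")
  expect_equal(fit$gamma_kjmolnm, gamma0, tolerance = 1e-12)
  expect_equal(fit$n_rims, 1)

  gridL <- seq(6, 6.6, by = 0.01)
  profL <- free_energy_profile(gridL, 10 * gridL)
  fitL <- fit_line_tension_profile(profL, mode = "rapid")
  expect_equal(fitL$gamma_pN, 10 * 1.66054 / 2, tolerance = 1e-5)

  flat <- free_energy_profile(gridL, rep(1, length(gridL)))
  expect_equal(fit_line_tension_profile(flat, mode = "rapid")$gamma_pN, 0,
               tolerance = 1e-12)
})

test_that("halves error is zero on identical halves and |e1-e2|/2 otherwise", {
  expect_equal(halves_error(rep(3.3, 100), mean), 0)
  expect_equal(halves_error(c(rep(10, 50), rep(12, 50)), mean), 1)
  w <- list(umbrella_window(0, 10, c(rep(1, 10), rep(3, 10))))
  est <- function(ws) mean(ws[[1]]$samples)
  expect_equal(halves_error(w, est), 1)
  expect_error(halves_error(numeric(1), mean), "at least two")
})

test_that("halves error shrinks with sample size on stationary windows", {
  # estimator on a fixed grid so its support cannot change with n:
  # free-energy difference between two interior points
  edges <- seq(-0.2, 0.2, length.out = 41)
  est <- function(ws) {
    p <- suppressWarnings(wham_solve(ws, edges = edges, min_count = 5))
    stats::approx(p$grid[p$sampled], p$G[p$sampled], xout = 0.12)$y -
      stats::approx(p$grid[p$sampled], p$G[p$sampled], xout = 0)$y
  }
  errs <- vapply(c(1e3, 1e4), function(n) {
    windows <- oracle_windows(centers = seq(-0.1, 0.1, length.out = 6),
                              n = n, seed = 31)
    halves_error(windows, est)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("bootstrap errors behave at their degenerate and calibrated ends", {
  windows <- oracle_windows(centers = seq(-0.2, 0.2, length.out = 6),
                            n = 1500, seed = 12)
  # n_boot = 1: documented degenerate case, zero errors
  p1 <- suppressWarnings(bootstrap_error(windows, n_boot = 1))
  expect_true(all(p1$err == 0))
  p <- suppressWarnings(bootstrap_error(windows, n_boot = 40, seed = 3))
  expect_true(all(p$err[p$sampled] >= 0, na.rm = TRUE))
  expect_gt(max(p$err, na.rm = TRUE), 0)
  # errors are calibrated against the analytic curve: most bins within 3 err
  g <- double_well()
  ok <- p$sampled & is.finite(p$err) & p$err > 0
  d <- p$G[ok] - g(p$grid[ok])
  d <- d - mean(d)
  expect_gt(mean(abs(d) < 3 * p$err[ok]), 0.6)
  expect_error(bootstrap_error(windows[1]), "two windows")
})

test_that("block convergence splits evenly and degenerates to the full solve", {
  windows <- oracle_windows(centers = seq(-0.2, 0.2, length.out = 6),
                            n = 1200, seed = 13)
  bc1 <- block_convergence(windows, 1)
  full <- wham_solve(windows, edges = bc1$profiles[[1]]$meta$edges)
  expect_equal(bc1$profiles[[1]]$G, full$G, tolerance = 1e-9)
  expect_equal(bc1$max_deviation, 0)

  bc <- block_convergence(windows, 2, n_bins = 60)
  expect_length(bc$profiles, 2L)
  expect_gt(bc$max_deviation, 0)
  expect_lt(bc$max_deviation, 1.5)

  bad <- windows
  bad[[1]]$samples <- bad[[1]]$samples[1:1001]
  expect_error(block_convergence(bad, 2, n_bins = 60), "divisible")
})

test_that("umbrella windows validate their inputs", {
  expect_error(umbrella_window(0, 0, 1:10), "kappa")
  expect_error(umbrella_window(0, 10, c(1, NA)), "finite")
})
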