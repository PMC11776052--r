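jittered_bilayer <- function(n_lipids = 20, seed = 3, amp = 0.03) {
  cfg <- build_flat_bilayer(geometry_spec(n_lipids = n_lipids,
                                          water_density = 0, seed = seed))
  cfg$positions <- cfg$positions +
    with_seed(seed, matrix(rnorm(3 * n_particles(cfg), 0, amp), ncol = 3))
  wrap_configuration(cfg)
}

test_that("every potential term matches central finite differences", {
  cfg <- jittered_bilayer()
  h <- 1e-6
  for (term in c("repulsion", "attraction", "bonds", "bends")) {
    ef <- energy_forces(cfg, terms = term)
    idx <- with_seed(11, sample(n_particles(cfg), 6))
    for (i in idx) for (k in 1:3) {
      cp <- cfg; cp$positions[i, k] <- cp$positions[i, k] + h
      cm <- cfg; cm$positions[i, k] <- cm$positions[i, k] - h
      fd <- -(energy_forces(cp, terms = term)$energy -
              energy_forces(cm, terms = term)$energy) / (2 * h)
      expect_lt(abs(fd - ef$forces[i, k]), 1e-4)
    }
  }
})

test_that("tail attraction is flat at its plateau edge and energies decompose", {
  # two parallel straight lipids whose tail beads sit exactly at the
  # plateau edge 2^(1/6) sigma: the attraction force vanishes there
  sep <- 2^(1 / 6)
  pos <- rbind(c(5, 5, 6.9), c(5, 5, 5.95), c(5, 5, 5),
               c(5 + sep, 5, 6.9), c(5 + sep, 5, 5.95), c(5 + sep, 5, 5))
  cfg <- particle_configuration(pos, rep(c("head", "tail", "terminal_tail"), 2),
                                rep(1:2, each = 3), c(12, 12, 12))
  ef <- energy_forces(cfg, terms = "attraction")
  # T-T and TT-TT pairs at the edge contribute -eps each; the two diagonal
  # T-TT pairs lie in the cos^2 shoulder
  expect_lt(ef$energy, -2 * 2.4)
  # force on the tail beads along x from their own edge pair is ~0; total
  # x-force equals the diagonal-pair contribution, equal and opposite
  expect_equal(sum(ef$forces[, 1]), 0, tolerance = 1e-9)
  ef_all <- energy_forces(cfg)
  expect_equal(ef_all$energy, sum(ef_all$terms), tolerance = 1e-9)

  # an isolated inert particle feels nothing
  lone <- particle_configuration(matrix(2, 1, 3), "water", NA_integer_,
                                 c(5, 5, 5))
  ef0 <- energy_forces(lone)
  expect_equal(ef0$energy, 0)
  expect_true(all(ef0$forces == 0))
})

test_that("overlapping beads trip the hard floor", {
  pos <- rbind(c(5, 5, 6.9), c(5, 5, 5.95), c(5, 5, 5),
               c(5.05, 5, 6.9), c(5.05, 5, 5.95), c(5.05, 5, 5))
  cfg <- particle_configuration(pos, rep(c("head", "tail", "terminal_tail"), 2),
                                rep(1:2, each = 3), c(12, 12, 12))
  expect_error(energy_forces(cfg), "hard floor")
})

test_that("zero friction and zero force give ballistic drift", {
  one <- particle_configuration(matrix(5, 1, 3), "water", NA_integer_,
                                c(20, 20, 20))
  st <- simulation_settings(n_steps = 1000, record_interval = 100,
                            timestep = 0.02, friction = 0, seed = 3)
  r <- run_langevin(one, settings = st, keep_water = TRUE)
  xs <- vapply(r$frames, function(f) f$positions[1, 1], numeric(1))
  steps <- diff(xs)
  expect_true(all(abs(diff(steps)) < 1e-9))   # constant velocity
  expect_gt(max(abs(steps)), 0)               # and it does move
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  cfg <- jittered_bilayer(8)
  st <- simulation_settings(n_steps = 500, record_interval = 100, seed = 9)
  r1 <- run_langevin(cfg, settings = st)
  r2 <- run_langevin(cfg, settings = st)
  expect_identical(r1$config$positions, r2$config$positions)
  r3 <- run_langevin(cfg, settings = modifyList(st, list(seed = 10L)))
  expect_false(identical(r1$config$positions, r3$config$positions))
})

test_that("a tethered particle samples the Boltzmann variance", {
  one <- particle_configuration(matrix(2.5, 1, 3), "water", NA_integer_,
                                c(5, 5, 5))
  k <- 50
  st <- simulation_settings(n_steps = 1e5, record_interval = 5,
                            timestep = 0.05, friction = 1, seed = 7)
  r <- run_langevin(one, settings = st, keep_water = TRUE,
                    biases = list(list(kind = "tether", k = k, index = 1L,
                                       ref = c(2.5, 2.5, 2.5))))
  xs <- vapply(r$frames, function(f) f$positions[1, 1:3], numeric(3))
  v <- mean(apply(xs - 2.5, 1, var))          # average over 3 dof
  expect_equal(v, 0.00831446 * 310 / k, tolerance = 0.05)
})

test_that("a stiff Full-Path window samples a narrow Gaussian at its center", {
  cfg <- build_flat_bilayer(geometry_spec(n_lipids = 60, area_per_lipid = 1.1,
                                          water_density = 0, seed = 1))
  st0 <- simulation_settings(n_steps = 4000, record_interval = 100,
                             timestep = 0.01, seed = 2)
  eq <- run_langevin(cfg, settings = st0)$config
  params <- calibrate_cv_eq(eq, cv_params())
  kappa <- 5e4
  st <- simulation_settings(n_steps = 20000, record_interval = 20,
                            timestep = 0.01, seed = 5)
  res <- run_window(eq, params, center = 0.05, kappa = kappa, settings = st,
                    keep_fraction = 0.5)
  samp <- res$window$samples
  sigma <- sqrt(0.00831446 * 310 / kappa)
  expect_lt(abs(mean(samp) - 0.05), 4 * sigma)
  expect_lt(sd(samp), 3 * sigma)              # bias dominates the landscape
  expect_gt(sd(samp), sigma / 3)

  # keep_fraction = 1 keeps every recorded sample
  res_all <- run_window(eq, params, center = 0.05, kappa = kappa,
                        settings = st, keep_fraction = 1)
  expect_equal(length(res_all$window$samples), nrow(res_all$series))
})

test_that("steered pulls drag the CV along the schedule", {
  cfg <- build_flat_bilayer(geometry_spec(n_lipids = 60, area_per_lipid = 1.1,
                                          water_density = 0, seed = 1))
  st0 <- simulation_settings(n_steps = 4000, record_interval = 100,
                             timestep = 0.01, seed = 2)
  eq <- run_langevin(cfg, settings = st0)$config
  params <- calibrate_cv_eq(eq, cv_params())
  st <- simulation_settings(n_steps = 20000, record_interval = 100,
                            timestep = 0.01, seed = 6)
  pull <- steered_pull(eq, params, schedule = c(0, 0.9), kappa = 5000,
                       settings = st)
  cvs <- pull$series$cv
  expect_gt(cor(seq_along(cvs), cvs, method = "spearman"), 0.8)
  expect_lt(abs(tail(cvs, 1) - 0.9), 3 * sqrt(0.00831446 * 310 / 5000) + 0.15)

  # a fixed schedule equals an ordinary window run with the same seed
  flatpull <- steered_pull(eq, params, schedule = c(0.05, 0.05), kappa = 5000,
                           settings = st)
  win <- run_langevin(eq, settings = st,
                      biases = list(list(kind = "fullpath", kappa = 5000,
                                         center_from = 0.05, center_to = 0.05,
                                         params = unclass(params))))
  expect_identical(flatpull$series$cv, win$series$cv)
})

test_that("settings and force-field constructors validate inputs", {
  expect_error(simulation_settings(timestep = 0), "timestep")
  expect_error(simulation_settings(temperature = -1), "temperature")
  expect_error(toy_forcefield(tail_attraction_eps = -1), "attraction")
  expect_error(run_langevin(particle_configuration(matrix(1, 1, 3), "water",
                                                   NA_integer_, c(5, 5, 5))),
               "no particles")
})
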