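# a lipid stack whose center of geometry sits exactly at z0, plus waters
with_waters <- function(water_z, box = c(6, 6, 10), z0 = 5) {
  lipid <- rbind(c(3, 3, z0 + 0.95), c(3, 3, z0), c(3, 3, z0 - 0.95))
  n_w <- length(water_z)
  pos <- rbind(lipid, cbind(rep(2, n_w), rep(2, n_w), water_z))
  particle_configuration(pos,
                         c("head", "tail", "terminal_tail", rep("water", n_w)),
                         c(1L, 1L, 1L, rep(NA_integer_, n_w)), box)
}

test_that("default slicing yields exactly 17 slices", {
  expect_equal(slice_spec()$n_slices, 17L)
  expect_error(slice_spec(interval = c(-2.1, 2.1), width = 0.25),
               "integer multiple")
  expect_error(slice_spec(width = -1), "width")
})

test_that("slice counts weight waters by proximity to slice centers", {
  spec <- slice_spec()
  expect_equal(slice_water_counts(with_waters(numeric(0)), spec),
               numeric(17))
  # one water exactly at the central slice center (offset 0 from the COG)
  counts <- slice_water_counts(with_waters(5), spec)
  expect_equal(counts[9], 1)
  expect_equal(sum(counts[-9]), 0)
  # off-center water weighs less than one
  counts2 <- slice_water_counts(with_waters(5 + 0.1), spec)
  expect_equal(counts2[9], exp(-0.1^2 / (2 * 0.1^2)), tolerance = 1e-12)
  # outside the interval: ignored
  expect_equal(sum(slice_water_counts(with_waters(8.5), spec)), 0)
})

test_that("pore state is the wet-slice fraction with a wet boundary", {
  spec <- slice_spec()
  expect_equal(pore_state_value(rep(2, 17), spec), 1)
  expect_equal(pore_state_value(rep(0, 17), spec), 0)
  expect_equal(pore_state_value(c(rep(2, 9), rep(0, 8)), spec), 9 / 17)
  expect_equal(pore_state_value(c(rep(1, 17)), spec), 1)  # theta(0) = 1
  expect_error(pore_state_value(rep(1, 5), spec), "length")
})

test_that("pore state is invariant to permutation and xy translation,
           and non-increasing under water removal", {
  cfg <- pore_fixture(1.5)
  spec <- slice_spec()
  s0 <- pore_state(cfg, spec)
  # permutation of water rows
  perm <- cfg
  iw <- which(perm$roles == "water")
  with_seed(3, {
    shuffle <- sample(iw)
    perm$positions[iw, ] <- perm$positions[shuffle, ]
  })
  expect_equal(pore_state(perm, spec), s0)
  # rigid xy translation (wrapped)
  shifted <- cfg
  shifted$positions[, 1] <- shifted$positions[, 1] + 1.3
  shifted <- wrap_configuration(shifted)
  expect_equal(pore_state(shifted, spec), s0)
  # removing waters never increases s
  with_seed(8, {
    cur <- cfg
    s_prev <- s0
    for (step in 1:10) {
      iw <- which(cur$roles == "water")
      drop <- sample(iw, length(iw) %/% 5)
      keep <- setdiff(seq_len(n_particles(cur)), drop)
      cur <- particle_configuration(cur$positions[keep, ], cur$roles[keep],
                                    cur$lipid_ids[keep], cur$box)
      s_new <- pore_state(cur, spec)
      expect_lte(s_new, s_prev + 1e-12)
      s_prev <- s_new
    }
  })
})

test_that("pore-state series and lifetime fit recover known parameters", {
  a0 <- 0.45; a1 <- 0.08; a2 <- 60
  t <- seq(0, 120, by = 1)
  s <- a0 * (1 - tanh(a1 * (t - a2)))
  fit <- fit_pore_lifetime(s, times = t)
  expect_equal(fit$A0, a0, tolerance = 1e-6)
  expect_equal(fit$A1, a1, tolerance = 1e-6)
  expect_equal(fit$A2, a2, tolerance = 1e-6)

  # seeded noise: lifetime recovered within 5% on average
  errs <- with_seed(21, vapply(1:20, function(i) {
    sn <- s + rnorm(length(s), 0, 0.05)
    abs(fit_pore_lifetime(sn, times = t)$A2 - a2) / a2
  }, numeric(1)))
  expect_lt(mean(errs), 0.05)

  expect_error(fit_pore_lifetime(rep(0.9, 50), times = 1:50), "closure")
  expect_error(fit_pore_lifetime(s[1:5], times = t[1:5]), "10 points")
})

test_that("distal tail density counts terminal beads per core volume", {
  # lipid stacks put exactly one TT bead each at the mid-plane
  cfg <- stacked_lipids(matrix(runif(10, -2, 2), 5, 2), box = c(10, 10, 12))
  # TT beads sit 0.95 nm below the stack center: probe wide enough
  d <- distal_tail_density(cfg, probe_radius = 1.2)
  expect_equal(d, 5 / (10 * 10 * 2 * 1.2), tolerance = 1e-12)
  # doubling the count doubles the density
  cfg2 <- stacked_lipids(matrix(runif(20, -2, 2), 10, 2), box = c(10, 10, 12))
  expect_equal(distal_tail_density(cfg2, probe_radius = 1.2), 2 * d,
               tolerance = 1e-12)
  # none in the region
  expect_equal(distal_tail_density(cfg, probe_radius = 0.1), 0)
  expect_error(distal_tail_density(list()), "empty")
})

test_that("pore fixtures drive the series machinery end to end", {
  cfg <- pore_fixture(1.5)
  ser <- pore_state_series(list(cfg, cfg), times = c(0, 1))
  expect_equal(ser$s_values, c(1, 1))
  expect_equal(dim(ser$occupancy), c(2L, 17L))
})
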