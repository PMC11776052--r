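# shared fixtures, built once per test run

with_seed <- porecv:::with_seed

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

flat_fixture <- function(n_lipids = 288, area = 0.64, seed = 1) {
  cached(sprintf("flat_%d_%g_%d", n_lipids, area, seed),
         build_flat_bilayer(geometry_spec(n_lipids = n_lipids,
                                          area_per_lipid = area, seed = seed)))
}

pore_fixture <- function(radius, n_lipids = 288, area = 0.64, seed = 1) {
  cached(sprintf("pore_%g_%d_%g_%d", radius, n_lipids, area, seed),
         build_pore_bilayer(geometry_spec(n_lipids = n_lipids,
                                          area_per_lipid = area,
                                          pore_radius = radius, seed = seed)))
}

calibrated_params <- function(n_lipids = 288, area = 0.64, seed = 1) {
  cached(sprintf("params_%d_%g_%d", n_lipids, area, seed),
         calibrate_cv_eq(flat_fixture(n_lipids, area, seed), cv_params()))
}

# a valid configuration whose tail beads sit at prescribed xy offsets from
# the box center: every lipid is a vertical H/T/TT stack at one xy site, so
# each site contributes two tail-role beads at that in-plane distance
stacked_lipids <- function(xy_offsets, box = c(12, 12, 12), z0 = box[3] / 2) {
  n <- nrow(xy_offsets)
  pos <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- box[1] / 2 + xy_offsets[i, 1]
    y <- box[2] / 2 + xy_offsets[i, 2]
    rbind(c(x, y, z0 + 0.95), c(x, y, z0), c(x, y, z0 - 0.95))
  }))
  particle_configuration(pos, rep(c("head", "tail", "terminal_tail"), n),
                         rep(seq_len(n), each = 3L), box)
}

# analytic double-well free energy used as the WHAM oracle
double_well <- function(a = 10) function(x) a * (x^2 - 1)^2

oracle_windows <- function(centers = seq(-0.36, 0.36, length.out = 20),
                           kappa = 5000, n = 5000, seed = 1,
                           g = double_well()) {
  with_seed(seed, lapply(centers, function(ct)
    umbrella_window(ct, kappa,
                    sample_biased_boltzmann(g, ct, kappa, n,
                                            lo = -1.5, hi = 1.5))))
}
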