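#' Toy bead-lipid force field
#'
#' A minimal implicit-solvent lipid model: three beads per lipid joined by
#' FENE bonds and a head-to-terminal straightening spring, purely repulsive
#' (WCA) cores on all lipid beads (heads slightly smaller to keep monolayers
#' flat), and a broadened cosine-squared attraction between tail beads that
#' provides the hydrophobic cohesion holding bilayers, pores and stripe rims
#' together. Water beads carry no interactions (implicit solvent). The unit
#' mapping is direct: bead size in nm, energies in kJ/mol, so all derived
#' quantities (line tension, free energies) come out in the package's
#' standard units.
#'
#' @param bead_diameter Tail bead diameter sigma in nm.
#' @param bond_stiffness FENE bond stiffness in kJ mol^-1 nm^-2.
#' @param bond_length FENE divergence (maximum) length in nm.
#' @param bend_stiffness Straightening spring constant in kJ mol^-1 nm^-2
#'   (harmonic in the head-terminal distance, rest length `4 * bead_diameter`).
#' @param tail_attraction_eps Depth of the tail-tail attraction in kJ/mol.
#'   The default (2.4) puts kT/eps near 1.07 at 310 K, inside the fluid
#'   bilayer regime of this model class.
#' @param tail_attraction_range Width w_c of the attraction tail in nm.
#' @param repulsion_eps WCA repulsion strength in kJ/mol.
#' @param head_diameter_factor Head bead diameter as a fraction of sigma.
#' @param overlap_floor Hard floor (fraction of the pair diameter) below
#'   which an overlap aborts the computation.
#'
#' @return An object of class `toy_forcefield`.
#' @export
toy_forcefield <- function(bead_diameter = 1, bond_stiffness = 75,
                           bond_length = 1.5, bend_stiffness = 24,
                           tail_attraction_eps = 2.4,
                           tail_attraction_range = 1.6, repulsion_eps = 2.4,
                           head_diameter_factor = 0.95, overlap_floor = 0.2) {
  if (tail_attraction_eps < 0) stop("`tail_attraction_eps` must be >= 0")
  if (bead_diameter <= 0 || bond_length <= 0)
    stop("geometric force-field parameters must be positive")
  structure(list(bead_diameter = bead_diameter,
                 bond_stiffness = bond_stiffness, bond_length = bond_length,
                 bend_stiffness = bend_stiffness,
                 tail_attraction_eps = tail_attraction_eps,
                 tail_attraction_range = tail_attraction_range,
                 repulsion_eps = repulsion_eps,
                 head_diameter_factor = head_diameter_factor,
                 overlap_floor = overlap_floor),
            class = "toy_forcefield")
}

#' Simulation settings for the toy Langevin engine
#'
#' @param temperature Temperature in K (default 310).
#' @param timestep Integration step in ps.
#' @param friction Langevin friction in 1/ps.
#' @param seed Integer seed of the noise stream; runs are deterministic for
#'   a fixed seed.
#' @param n_steps Number of integration steps.
#' @param mass Bead mass in amu (1 kJ/mol = 1 amu nm^2 ps^-2).
#' @param record_interval Steps between recorded frames / CV samples.
#' @param piston_interval Steps between piston moves when the rim-axis box
#'   edge is biased.
#' @param piston_mobility Mobility of the overdamped box piston in
#'   nm^2 mol kJ^-1 ps^-1.
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(temperature = 310, timestep = 0.02,
                                friction = 1, seed = 1L, n_steps = 1000L,
                                mass = 100, record_interval = 50L,
                                piston_interval = 10L,
                                piston_mobility = 2e-4) {
  if (timestep <= 0) stop("`timestep` must be > 0")
  if (temperature <= 0) stop("`temperature` must be > 0")
  structure(list(temperature = temperature, timestep = timestep,
                 friction = friction, seed = as.integer(seed),
                 n_steps = as.integer(n_steps), mass = mass,
                 record_interval = as.integer(record_interval),
                 piston_interval = as.integer(piston_interval),
                 piston_mobility = piston_mobility),
            class = "simulation_settings")
}

#' Energy and forces of the toy force field
#'
#' @param config A [particle_configuration()] (water beads are inert).
#' @param ff A [toy_forcefield()].
#' @param terms Character subset of
#'   `c("repulsion", "attraction", "bonds", "bends")` to evaluate.
#' @return List with `energy` (kJ/mol), `terms` (named per-term energies)
#'   and `forces` (n x 3 matrix, kJ mol^-1 nm^-1, exact negative gradients).
#' @export
energy_forces <- function(config, ff = toy_forcefield(),
                          terms = c("repulsion", "attraction", "bonds",
                                    "bends")) {
  all_terms <- c("repulsion", "attraction", "bonds", "bends")
  terms <- match.arg(terms, all_terms, several.ok = TRUE)
  cpp_energy_forces(config$positions, role_codes(config$roles),
                    config$lipid_ids, config$box, unclass(ff),
                    all_terms %in% terms)
}

strip_water <- function(config) {
  keep <- config$roles != "water"
  if (all(keep)) return(config)
  particle_configuration(config$positions[keep, , drop = FALSE],
                         config$roles[keep], config$lipid_ids[keep],
                         config$box, config$periodic)
}

series_to_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- colnames(m)
  df
}

#' Run Langevin dynamics with optional biases
#'
#' BAOAB Langevin integration of the toy force field. Water beads are
#' removed before integration (the model is implicit-solvent; water markers
#' exist only for occupancy observables). Supported biases: a (moving)
#' harmonic restraint on the Full-Path CV, an overdamped piston that biases
#' the rim-axis box edge with affine rescaling, a flat-bottom restraint on
#' head beads along an axis relative to the lipid center of mass, and a
#' harmonic position tether (used in tests).
#'
#' @param config Starting [particle_configuration()].
#' @param ff A [toy_forcefield()].
#' @param settings A [simulation_settings()].
#' @param biases List of bias descriptors (see [bias_spec()] helpers and
#'   the internal kinds documented in the vignette).
#' @param keep_water Keep water beads as free non-interacting particles
#'   instead of stripping them (useful for ideal-gas/tether checks).
#' @return List with `config` (final state), `frames` (list of
#'   [particle_configuration()] snapshots), `series` (data.frame of recorded
#'   times, CV components and/or box edge), and `boxes` (per-frame box
#'   matrix).
#' @export
run_langevin <- function(config, ff = toy_forcefield(),
                         settings = simulation_settings(), biases = list(),
                         keep_water = FALSE) {
  if (!keep_water) config <- strip_water(config)
  if (n_particles(config) == 0L)
    stop("no particles left to integrate")
  res <- cpp_run_langevin(config$positions, role_codes(config$roles),
                          config$lipid_ids, config$box, unclass(ff),
                          unclass(settings), biases)
  frames <- lapply(seq_along(res$frames), function(i) {
    particle_configuration(res$frames[[i]], config$roles, config$lipid_ids,
                           res$frame_boxes[i, ], config$periodic)
  })
  final <- particle_configuration(res$positions, config$roles,
                                  config$lipid_ids, res$box, config$periodic)
  list(config = final, frames = frames, series = series_to_df(res$series),
       boxes = res$frame_boxes)
}

fullpath_bias <- function(params, kappa, center_from, center_to = center_from) {
  if (!is.finite(params$cv_eq) || params$cv_eq <= 0)
    stop("Full-Path bias requires calibrated `cv_eq`")
  list(kind = "fullpath", kappa = kappa, center_from = center_from,
       center_to = center_to, params = unclass(params))
}

#' Steered pull along the Full-Path CV
#'
#' Runs moving-harmonic-biased dynamics with the bias center moving linearly
#' from `schedule[1]` to `schedule[2]` over the run, recording the joint CV
#' and its components; the returned frames are suitable for umbrella-window
#' seeding with [seed_windows()].
#'
#' @param config Starting configuration.
#' @param params Calibrated [cv_params()].
#' @param schedule Length-2 numeric: initial and final bias center. Must be
#'   monotone in the sense of a single sweep (any direction).
#' @param kappa Bias force constant in kJ/mol per CV^2 (default 5000).
#' @param ff,settings Engine parameters.
#' @return As [run_langevin()]; `series` carries columns
#'   `time, cv, cv_cyl, cv_radius, s1, s2, bias_center`.
#' @export
steered_pull <- function(config, params, schedule, kappa = 5000,
                         ff = toy_forcefield(),
                         settings = simulation_settings()) {
  if (length(schedule) != 2L || any(!is.finite(schedule)))
    stop("`schedule` must be two finite CV values")
  run_langevin(config, ff, settings,
               biases = list(fullpath_bias(params, kappa, schedule[1],
                                           schedule[2])))
}

#' Run one umbrella window on the Full-Path CV
#'
#' Fixed-center harmonic-biased dynamics; an initial fraction of the
#' recorded series is discarded as equilibration (by default the last 25%
#' is kept, mirroring a production-tail analysis policy).
#'
#' @param config Starting configuration (typically a steered-pull frame).
#' @param params Calibrated [cv_params()].
#' @param center Bias center.
#' @param kappa Force constant (default 5000).
#' @param ff,settings Engine parameters.
#' @param keep_fraction Fraction of the recorded series kept from the end.
#' @return List with `window` (an [umbrella_window()] holding the kept CV
#'   samples), `series` (full recorded data.frame) and `config` (final
#'   state).
#' @export
run_window <- function(config, params, center, kappa = 5000,
                       ff = toy_forcefield(),
                       settings = simulation_settings(),
                       keep_fraction = 0.25) {
  res <- run_langevin(config, ff, settings,
                      biases = list(fullpath_bias(params, kappa, center)))
  samp <- keep_tail(res$series$cv, keep_fraction)
  list(window = umbrella_window(center, kappa, samp,
                                temperature = settings$temperature),
       series = res$series, config = res$config)
}

#' Run one rim-length (box-edge) umbrella window on a stripe
#'
#' Biases the box edge along the rim axis (y) with a harmonic restraint via
#' an overdamped piston, keeping the stripe centered with a flat-bottom
#' restraint on head beads along the membrane normal (x).
#'
#' @param config Starting stripe configuration.
#' @param center Target box edge (nm).
#' @param kappa Force constant in kJ mol^-1 nm^-2 (default 5000).
#' @param ff,settings Engine parameters.
#' @param keep_fraction Fraction of the recorded series kept from the end.
#' @param flat_bottom Optional [bias_spec()] of kind `flat_bottom`; defaults
#'   to the standard k_fb = 1000 kJ mol^-1 nm^-2, half-width 2.5 nm.
#' @return As [run_window()], with samples of the box edge (nm).
#' @export
run_rim_window <- function(config, center, kappa = 5000,
                           ff = toy_forcefield(),
                           settings = simulation_settings(),
                           keep_fraction = 0.25,
                           flat_bottom = bias_spec("flat_bottom")) {
  biases <- list(list(kind = "piston", kappa = kappa, center = center,
                      mobility = settings$piston_mobility,
                      interval = settings$piston_interval))
  if (!is.null(flat_bottom))
    biases <- c(biases, list(list(kind = "flat_bottom", axis = 1L,
                                  k_fb = flat_bottom$k_fb,
                                  half_width = flat_bottom$half_width)))
  res <- run_langevin(config, ff, settings, biases)
  samp <- keep_tail(res$series$box_rim, keep_fraction)
  list(window = umbrella_window(center, kappa, samp,
                                temperature = settings$temperature),
       series = res$series, config = res$config)
}

keep_tail <- function(x, fraction) {
  if (fraction <= 0 || fraction > 1) stop("`keep_fraction` must be in (0, 1]")
  n <- length(x)
  x[seq.int(max(1L, n - floor(fraction * n) + 1L), n)]
}
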