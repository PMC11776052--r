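#' Line tension of a toy lipid stripe, end to end
#'
#' Builds a stripe, equilibrates it briefly, runs a ladder of rim-length
#' umbrella windows (middle-out, each window chained from its neighbor's
#' final state), solves WHAM over the box-edge samples, and fits the line
#' tension from the slope of the linear profile (two rims).
#'
#' @param n_lipids Stripe size (default 60).
#' @param ff A [toy_forcefield()].
#' @param seed Master seed; window `i` uses `seed + i`.
#' @param n_windows Number of evenly spaced windows (default 11).
#' @param half_range Window centers span `L0 +/- half_range` nm around the
#'   built rim length `L0` (default 0.3).
#' @param kappa Box-edge force constant in kJ mol^-1 nm^-2 (default 5000).
#' @param n_steps Steps per window.
#' @param equil_steps Unbiased pre-equilibration steps.
#' @param settings Base [simulation_settings()]; its seed/n_steps fields are
#'   overridden per stage.
#' @param keep_fraction Production tail kept per window (default 0.25).
#' @param n_bins WHAM bins over the rim-length range (default 40; use fewer
#'   for very short exploratory runs so bins keep enough samples).
#' @return List with `fit` (a `line_tension_result`), `profile`
#'   (a [free_energy_profile()] over the rim length), `windows`, and
#'   `halves_err_pN` (halves-based error of the fitted line tension).
#' @export
rapid_line_tension <- function(n_lipids = 60, ff = toy_forcefield(),
                               seed = 1L, n_windows = 11, half_range = 0.3,
                               kappa = 5000, n_steps = 30000,
                               equil_steps = 10000,
                               settings = simulation_settings(timestep = 0.01,
                                                              record_interval = 25),
                               keep_fraction = 0.25, n_bins = 40) {
  spec <- geometry_spec(n_lipids = n_lipids, area_per_lipid = 1.1,
                        stripe = TRUE, water_density = 0, seed = seed)
  stripe <- build_stripe(spec)
  L0 <- stripe$box[2]
  centers <- make_window_centers(L0 - half_range, L0 + half_range,
                                 n = n_windows)
  st <- settings
  st$seed <- as.integer(seed)
  st$n_steps <- as.integer(equil_steps)
  state0 <- run_langevin(stripe, ff, st)$config

  windows <- vector("list", length(centers))
  mid <- which.min(abs(centers - L0))
  run_one <- function(state, w) {
    stw <- settings
    stw$seed <- as.integer(seed + w)
    stw$n_steps <- as.integer(n_steps)
    run_rim_window(state, centers[w], kappa = kappa, ff = ff,
                   settings = stw, keep_fraction = keep_fraction)
  }
  state <- state0
  for (w in mid:1) {                     # middle-out, downward leg
    res <- run_one(state, w)
    windows[[w]] <- res$window
    state <- res$config
  }
  state <- state0
  for (w in (mid + 1):length(centers)) { # upward leg
    res <- run_one(state, w)
    windows[[w]] <- res$window
    state <- res$config
  }
  profile <- wham_solve(windows, n_bins = n_bins)
  fit <- fit_line_tension_profile(profile, mode = "rapid")
  gamma_est <- function(ws) {
    p <- suppressWarnings(wham_solve(ws, n_bins = n_bins))
    fit_line_tension_profile(p, mode = "rapid")$gamma_pN
  }
  err <- tryCatch(halves_error(windows, gamma_est), error = function(e) NA_real_)
  list(fit = fit, profile = profile, windows = windows, halves_err_pN = err,
       centers = centers)
}

#' Full-Path free-energy profile on a toy bilayer, end to end
#'
#' Calibrates CV_eq on a short unbiased run of a flat toy bilayer, steers
#' the Full-Path CV across `cv_range`, seeds umbrella windows from the pull
#' (forward order, or reverse for hysteresis checks), runs every window
#' with a fixed-center harmonic bias, and solves WHAM.
#'
#' @param n_lipids Bilayer size (default 60).
#' @param cv_range Length-2 CV interval covered by the windows; its span
#'   must be a multiple of `spacing`.
#' @param spacing Window spacing in CV units (default 0.035, matched to
#'   kappa = 5000 so adjacent windows overlap).
#' @param kappa Force constant in kJ/mol per CV^2 (default 5000).
#' @param overshoot How far the steering schedule extends beyond
#'   `cv_range` on both ends so every window center lies inside the
#'   recorded pull (default 0.05).
#' @param reverse Steer from `cv_range[2]` down to `cv_range[1]` instead
#'   (the pull starts from the final state of a forward pull).
#' @param seed Master seed; stage `i` uses `seed + i`.
#' @param steer_steps,window_steps,equil_steps Steps per stage.
#' @param ff A [toy_forcefield()].
#' @param settings Base [simulation_settings()].
#' @param params A [cv_params()]; `cv_eq` is calibrated here when unset.
#' @param start Optional starting [particle_configuration()] overriding the
#'   built flat bilayer (used for reverse pulls).
#' @param keep_fraction Production tail kept per window.
#' @return List with `profile`, `windows`, `params` (calibrated), `pull`
#'   (steered series), `final` (last window state) and `halves_err`
#'   (halves-based error of the quadratic coefficient, kJ/mol).
#' @export
fullpath_profile <- function(n_lipids = 60, cv_range = c(-0.05, 0.895),
                             spacing = 0.035, kappa = 5000, reverse = FALSE,
                             overshoot = 0.05, seed = 1L, steer_steps = 40000,
                             window_steps = 20000, equil_steps = 10000,
                             ff = toy_forcefield(),
                             settings = simulation_settings(timestep = 0.02,
                                                            record_interval = 25),
                             params = cv_params(), start = NULL,
                             keep_fraction = 0.25) {
  st <- function(stage, n) {
    s <- settings
    s$seed <- as.integer(seed + stage)
    s$n_steps <- as.integer(n)
    s
  }
  calib_frames <- NULL
  if (is.null(start)) {
    spec <- geometry_spec(n_lipids = n_lipids, area_per_lipid = 1.1,
                          water_density = 0, seed = seed)
    eq <- run_langevin(build_flat_bilayer(spec), ff, st(0, equil_steps))
    start <- eq$config
    calib_frames <- tail(eq$frames, max(1L, length(eq$frames) %/% 2L))
  }
  if (!is.finite(params$cv_eq))
    params <- calibrate_cv_eq(if (is.null(calib_frames)) start else calib_frames,
                              params)

  wide <- cv_range + c(-1, 1) * overshoot
  schedule <- if (reverse) rev(wide) else wide
  pull <- steered_pull(start, params, schedule, kappa = kappa, ff = ff,
                       settings = st(1, steer_steps))
  centers <- make_window_centers(cv_range[1], cv_range[2], spacing = spacing)
  idx <- seed_windows(pull$frames, pull$series$cv, centers)
  n_windows <- length(centers)
  windows <- vector("list", n_windows)
  state <- NULL
  for (w in seq_len(n_windows)) {
    res <- run_window(pull$frames[[idx[w]]], params, centers[w],
                      kappa = kappa, ff = ff,
                      settings = st(1 + w, window_steps),
                      keep_fraction = keep_fraction)
    windows[[w]] <- res$window
    state <- res$config
  }
  profile <- wham_solve(windows, n_bins = 40)
  k_est <- function(ws) {
    p <- suppressWarnings(wham_solve(ws, n_bins = 40))
    fit_quadratic(p)$k
  }
  halves_err <- tryCatch(halves_error(windows, k_est),
                         error = function(e) NA_real_)
  list(profile = profile, windows = windows, params = params,
       pull = pull$series, final = state, halves_err = halves_err,
       centers = centers)
}
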