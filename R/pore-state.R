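#' Slice specification for the pore-state observable
#'
#' The membrane core is split into slices along the normal (z) axis,
#' centered around the lipid center of geometry. The default interval
#' `[-2.125, 2.125]` nm with 0.25 nm slices yields exactly 17 slices —
#' slightly exceeding the membrane thickness to allow for undulations.
#'
#' @param interval Length-2 numeric, slice interval relative to the lipid
#'   center of geometry (nm).
#' @param width Slice width (nm); `(interval[2] - interval[1]) / width`
#'   must be an integer.
#' @param kernel_bandwidth Gaussian smoothing bandwidth (nm) that weights
#'   water molecules by proximity to the slice center.
#' @param occupancy_threshold Weighted molecule count at or above which a
#'   slice counts as wet (default 1).
#' @return An object of class `slice_spec` with an `n_slices` field.
#' @export
slice_spec <- function(interval = c(-2.125, 2.125), width = 0.25,
                       kernel_bandwidth = 0.1, occupancy_threshold = 1) {
  if (width <= 0) stop("`width` must be > 0")
  span <- interval[2] - interval[1]
  ns <- span / width
  if (abs(ns - round(ns)) > 1e-9)
    stop("`interval` width must be an integer multiple of `width`")
  structure(list(interval = interval, width = width,
                 kernel_bandwidth = kernel_bandwidth,
                 occupancy_threshold = occupancy_threshold,
                 n_slices = as.integer(round(ns))),
            class = "slice_spec")
}

#' Gaussian-weighted water counts per membrane slice
#'
#' For every slice, sums a peak-normalized Gaussian weight of each water
#' particle's z-offset from the slice center (truncated at the slice
#' boundaries), so a molecule exactly at a slice center counts as one and
#' molecules near the edges count less. Slices are positioned relative to
#' the instantaneous lipid center of geometry.
#'
#' @param config A [particle_configuration()] containing water particles.
#' @param spec A [slice_spec()].
#' @return Numeric vector of length `spec$n_slices`.
#' @export
slice_water_counts <- function(config, spec = slice_spec()) {
  ns <- spec$n_slices
  is_w <- config$roles == "water"
  counts <- numeric(ns)
  if (!any(is_w)) return(counts)
  z0 <- lipid_center(config)[3]
  dz <- config$positions[is_w, 3] - z0
  lo <- spec$interval[1]
  idx <- floor((dz - lo) / spec$width) + 1
  keep <- idx >= 1 & idx <= ns & dz >= lo & dz <= spec$interval[2]
  if (!any(keep)) return(counts)
  idx <- idx[keep]
  off <- dz[keep] - (lo + (idx - 0.5) * spec$width)
  w <- exp(-off^2 / (2 * spec$kernel_bandwidth^2))
  v <- tapply(w, factor(idx, levels = seq_len(ns)), sum)
  counts <- as.numeric(ifelse(is.na(v), 0, v))
  counts
}

#' Pore state from slice counts
#'
#' Applies a Heaviside step (with the boundary counted as wet) to every
#' slice count and averages: `s = (1/N_S) * sum_i theta(count_i -
#' threshold)`, so `s = 1` for a continuous transmembrane water column and
#' `s = 0` for a fully dry core.
#'
#' @param counts Per-slice counts from [slice_water_counts()].
#' @param spec A [slice_spec()].
#' @return Pore-state value in `[0, 1]` (a multiple of `1/N_S`).
#' @export
pore_state_value <- function(counts, spec = slice_spec()) {
  if (length(counts) != spec$n_slices)
    stop("`counts` length must equal the number of slices")
  mean(counts >= spec$occupancy_threshold)
}

#' Pore state of a configuration
#'
#' Convenience wrapper: [slice_water_counts()] followed by
#' [pore_state_value()].
#'
#' @inheritParams slice_water_counts
#' @return Pore-state value in `[0, 1]`.
#' @export
pore_state <- function(config, spec = slice_spec()) {
  pore_state_value(slice_water_counts(config, spec), spec)
}

#' Pore-state time series over a trajectory
#'
#' @param frames List of [particle_configuration()] frames.
#' @param times Numeric times in ps (defaults to the frame index).
#' @param spec A [slice_spec()].
#' @return An object of class `pore_state_series`: list with `times`,
#'   `s_values`, and the per-slice `occupancy` matrix (frames x slices).
#' @export
pore_state_series <- function(frames, times = NULL, spec = slice_spec()) {
  if (inherits(frames, "particle_configuration")) frames <- list(frames)
  if (is.null(times)) times <- seq_along(frames) - 1
  occ <- t(vapply(frames, slice_water_counts, numeric(spec$n_slices),
                  spec = spec))
  s <- apply(occ, 1, pore_state_value, spec = spec)
  structure(list(times = times, s_values = s, occupancy = occ, spec = spec),
            class = "pore_state_series")
}

#' Fit the pore lifetime from a pore-state time series
#'
#' Nonlinear least-squares fit of the sigmoidal decay
#' `s(t) = A0 * (1 - tanh(A1 * (t - A2)))`, whose inflection point `A2` is
#' the pore lifetime; `A0` (half the initial plateau) and `A1` (closure
#' rate) are the other optimized parameters. `A2` is initialized at the
#' first time `s` drops below half its initial plateau.
#'
#' @param series A [pore_state_series()], or a numeric vector of s values
#'   (with `times` supplied).
#' @param times Numeric times when `series` is a plain vector.
#' @return List with `A0`, `A1`, `A2`, standard errors (`se`), and the
#'   underlying `nls` fit object.
#' @export
fit_pore_lifetime <- function(series, times = NULL) {
  if (inherits(series, "pore_state_series")) {
    s <- series$s_values; t <- series$times
  } else {
    s <- as.numeric(series); t <- times
  }
  if (is.null(t) || length(t) != length(s))
    stop("matching `times` are required")
  if (length(s) < 10L) stop("lifetime fit needs at least 10 points")
  plateau <- mean(head(s, max(3L, length(s) %/% 20L)))
  if (min(s) > 0.6 * plateau || plateau <= 0)
    stop("series shows no pore closure (s never decreases enough to fit)")
  i_half <- which(s < plateau / 2)[1]
  a2_0 <- if (is.na(i_half)) stats::median(t) else t[i_half]
  a1_0 <- 4 / max(diff(range(t)) / 10, .Machine$double.eps)
  df <- data.frame(t = t, s = s)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ A0 * (1 - tanh(A1 * (t - A2))), data = df,
                      start = list(A0 = plateau / 2, A1 = a1_0, A2 = a2_0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("lifetime fit failed to converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  list(A0 = unname(cf["A0"]), A1 = unname(cf["A1"]), A2 = unname(cf["A2"]),
       se = se, fit = fit)
}

#' Time-averaged density of terminal tail beads in the membrane core
#'
#' The average number density of distal (terminal) tail beads within
#' `|z - midplane| < probe_radius`, per frame and averaged over the
#' trajectory — the structural observable that correlates with pore
#' lifetime.
#'
#' @param frames List of [particle_configuration()] frames.
#' @param probe_radius Half-thickness of the probed core region (nm).
#' @return Mean density in particles/nm^3.
#' @export
distal_tail_density <- function(frames, probe_radius = 0.5) {
  if (inherits(frames, "particle_configuration")) frames <- list(frames)
  if (!length(frames)) stop("empty trajectory")
  dens <- vapply(frames, function(fr) {
    if (!any(fr$roles == "terminal_tail"))
      stop("configuration has no terminal_tail beads")
    z0 <- lipid_center(fr)[3]
    tt <- fr$roles == "terminal_tail"
    n_in <- sum(abs(fr$positions[tt, 3] - z0) < probe_radius)
    n_in / (fr$box[1] * fr$box[2] * 2 * probe_radius)
  }, numeric(1))
  mean(dens)
}
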