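#' Bias (restraint) specification
#'
#' Describes the restraints used by the umbrella-sampling machinery: a fixed
#' or moving harmonic bias on a CV, or a flat-bottom restraint used to keep
#' stripe systems from drifting/rotating along the membrane normal.
#'
#' @param kind One of `"harmonic"`, `"moving_harmonic"`, `"flat_bottom"`.
#' @param center Bias center in CV units; for `moving_harmonic` a function
#'   of time (ps) returning the instantaneous center.
#' @param kappa Harmonic force constant in kJ/mol per squared CV unit
#'   (default 5000).
#' @param k_fb Flat-bottom force constant in kJ mol^-1 nm^-2 (default 1000).
#' @param half_width Flat-bottom half width in nm (default 2.5).
#' @return An object of class `bias_spec`.
#' @export
bias_spec <- function(kind = c("harmonic", "moving_harmonic", "flat_bottom"),
                      center = 0, kappa = 5000, k_fb = 1000,
                      half_width = 2.5) {
  kind <- match.arg(kind)
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (k_fb < 0) stop("`k_fb` must be >= 0")
  if (half_width <= 0) stop("`half_width` must be > 0")
  structure(list(kind = kind, center = center, kappa = kappa, k_fb = k_fb,
                 half_width = half_width),
            class = "bias_spec")
}

#' Rim-length collective variable of a stripe
#'
#' The box edge length along the pore-rim axis. The CV depends only on the
#' box, not on particle positions: biasing it stretches or compresses both
#' rims of the stripe at once.
#'
#' @param config A [particle_configuration()].
#' @param axis Rim axis, `"x"`, `"y"` (default) or `"z"`.
#' @return Box edge length in nm.
#' @export
rim_length_cv <- function(config, axis = "y") {
  k <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  if (!config$periodic[k])
    stop("the rim axis must be periodic")
  config$box[k]
}

#' Harmonic bias energy and derivative
#'
#' `U = kappa/2 (cv - center)^2` with `dU/dcv = kappa (cv - center)`. For a
#' `moving_harmonic` spec the center is evaluated from the schedule at the
#' supplied time.
#'
#' @param cv CV value.
#' @param spec A [bias_spec()] of kind `harmonic` or `moving_harmonic`.
#' @param time Time in ps (needed for a moving center).
#' @return Named numeric vector `c(energy, dudcv)` in kJ/mol and kJ/mol per
#'   CV unit.
#' @export
harmonic_bias <- function(cv, spec, time = NULL) {
  if (!spec$kind %in% c("harmonic", "moving_harmonic"))
    stop("`spec` must be a (moving) harmonic bias")
  center <- spec$center
  if (spec$kind == "moving_harmonic") {
    if (!is.function(center))
      stop("a moving_harmonic bias needs `center` as a function of time")
    if (is.null(time)) stop("`time` is required for a moving bias")
    center <- center(time)
  }
  d <- cv - center
  c(energy = 0.5 * spec$kappa * d^2, dudcv = spec$kappa * d)
}

#' Flat-bottom bias energy and force
#'
#' Zero inside `|x - x_ref| <= half_width`, harmonic outside; the force is
#' continuous (zero) at the boundary. In the toy engine this acts on head
#' beads along the membrane normal relative to the stripe center of mass.
#'
#' @param x Position coordinate (nm).
#' @param x_ref Reference coordinate (nm).
#' @param spec A [bias_spec()] of kind `flat_bottom`.
#' @return Named numeric vector `c(energy, force)` (kJ/mol, kJ mol^-1 nm^-1).
#' @export
flat_bottom_bias <- function(x, x_ref, spec) {
  if (spec$kind != "flat_bottom") stop("`spec` must be a flat_bottom bias")
  d <- x - x_ref
  ad <- abs(d)
  ex <- pmax(ad - spec$half_width, 0)
  c(energy = 0.5 * spec$k_fb * ex^2,
    force = -spec$k_fb * ex * sign(d))
}

#' Convert a free-energy slope to a line tension
#'
#' For a stripe stretched along its rim axis the free energy grows linearly
#' with the rim length; the slope `m` (kJ mol^-1 nm^-1) divided by the
#' number of rims gives the line tension per rim. Expressed per molecule
#' (division by the Avogadro constant) this is reported in pN via
#' 1 kJ mol^-1 nm^-1 = 1.66054 pN.
#'
#' @param slope_m Fitted slope in kJ mol^-1 nm^-1.
#' @param n_rims Number of rims sharing the slope: 2 for a stripe, 1 for a
#'   single circular rim fit.
#' @param error Optional error on the slope (same units), propagated
#'   linearly.
#' @return An object of class `line_tension_result` with fields `slope_m`,
#'   `gamma_kjmolnm`, `gamma_pN`, `error` (pN) and `n_rims`.
#' @export
line_tension_from_slope <- function(slope_m, n_rims = 2, error = 0) {
  if (!is.finite(slope_m)) stop("`slope_m` must be finite")
  if (!n_rims %in% c(1, 2)) stop("`n_rims` must be 1 or 2")
  g <- slope_m / n_rims
  structure(list(slope_m = slope_m,
                 gamma_kjmolnm = g,
                 gamma_pN = g * .pN_per_kjmolnm,
                 error = abs(error) / n_rims * .pN_per_kjmolnm,
                 n_rims = n_rims),
            class = "line_tension_result")
}

#' Convert between kJ/mol/nm and pN line-tension units
#'
#' @param x Numeric values.
#' @param from Unit of `x`: `"kjmolnm"` or `"pN"`.
#' @return Converted values.
#' @export
line_tension_units <- function(x, from = c("kjmolnm", "pN")) {
  from <- match.arg(from)
  if (from == "kjmolnm") x * .pN_per_kjmolnm else x / .pN_per_kjmolnm
}

#' @export
print.line_tension_result <- function(x, ...) {
  cat(sprintf("<line_tension> %.3f pN (%.3f kJ/mol/nm, slope %.3f over %d rim%s)",
              x$gamma_pN, x$gamma_kjmolnm, x$slope_m, x$n_rims,
              if (x$n_rims > 1) "s" else ""))
  if (is.finite(x$error) && x$error > 0) cat(sprintf(" +/- %.3f pN", x$error))
  cat("\n")
  invisible(x)
}
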