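#' Parameters of the Full-Path collective variable
#'
#' Collects every symbol of the joint pore CV: the defect cylinder radius,
#' the calibrated equilibrium cylinder count, the switching threshold and
#' rate, the pore-radius unit, and the numerical knobs of the soft minimum
#' and the rational membership function.
#'
#' @param r_cyl Cylinder radius in nm (default 1.2).
#' @param cv_eq Equilibrium soft count of tail beads inside the cylinder for
#'   an intact bilayer; set by [calibrate_cv_eq()] (default `NA`).
#' @param cv0 Switching threshold; must lie in (0.5, 1) so that the blend
#'   hands over after defect formation but before a full pore (default 0.95).
#' @param alpha Switching rate (default 20).
#' @param r_unit Pore radius unit in nm; `cv_radius = r_min / r_unit`
#'   (default 1).
#' @param softmin_beta Sharpness of the converging-sum soft minimum in nm
#'   (default 50). Larger values track the true minimum more closely.
#' @param boundary_exponents Integer pair (n, m) of the rational membership
#'   function around `r_cyl` (default `c(6, 12)`).
#' @param dist_floor Distance floor in nm applied inside the soft minimum to
#'   avoid overflow (default 1e-3).
#'
#' @return An object of class `cv_params`.
#' @export
cv_params <- function(r_cyl = 1.2, cv_eq = NA_real_, cv0 = 0.95, alpha = 20,
                      r_unit = 1, softmin_beta = 50,
                      boundary_exponents = c(6L, 12L), dist_floor = 1e-3) {
  if (!(cv0 > 0.5 && cv0 < 1))
    stop("`cv0` must lie strictly between 0.5 and 1")
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (r_cyl <= 0) stop("`r_cyl` must be > 0")
  if (!is.na(cv_eq) && cv_eq <= 0) stop("`cv_eq` must be > 0")
  if (softmin_beta <= 0) stop("`softmin_beta` must be > 0")
  if (r_unit <= 0) stop("`r_unit` must be > 0")
  if (dist_floor <= 0) stop("`dist_floor` must be > 0")
  be <- as.integer(boundary_exponents)
  if (length(be) != 2L || any(be < 1L) || be[1] >= be[2])
    stop("`boundary_exponents` must be an increasing integer pair (n, m)")
  structure(list(r_cyl = r_cyl, cv_eq = cv_eq, cv0 = cv0, alpha = alpha,
                 r_unit = r_unit, softmin_beta = softmin_beta,
                 boundary_exponents = be, dist_floor = dist_floor),
            class = "cv_params")
}

#' Complementary switching function pair
#'
#' The smooth logistic pair `s1(x) = 1 / (1 + exp(alpha (x - cv0)))`,
#' `s2 = 1 - s1`. The two functions intersect at `cv0` (where both equal
#' 0.5) and `alpha` sets how fast they transition between 0 and 1.
#'
#' @param x Numeric vector of switch-argument values.
#' @param cv0 Intersection threshold.
#' @param alpha Transition rate (> 0).
#' @return A list with numeric vectors `s1` and `s2`.
#' @export
switching_pair <- function(x, cv0 = 0.95, alpha = 20) {
  if (alpha <= 0) stop("`alpha` must be > 0")
  s1 <- stats::plogis(-alpha * (x - cv0))
  list(s1 = s1, s2 = 1 - s1)
}

resolve_center <- function(config, center) {
  if (is.null(center)) config$box[1:2] / 2 else as.numeric(center)[1:2]
}

tail_check <- function(config) {
  if (!any(config$roles %in% c("tail", "terminal_tail")))
    stop("configuration contains no tail-role beads")
}

#' Soft count of tail beads inside the defect cylinder
#'
#' Sums a smooth radial membership weight over all tail and terminal-tail
#' beads, where the weight is the rational function of the minimum-image xy
#' distance to the cylinder axis, equal to 1 on the axis and decaying around
#' `r_cyl`. The cylinder spans the whole box in z.
#'
#' @param config A [particle_configuration()].
#' @param params A [cv_params()].
#' @param center Optional xy cylinder axis (nm); defaults to the box
#'   xy-center (builders produce membranes centered there, and under a bias
#'   the pore localizes at the cylinder).
#' @return The soft count `d` (dimensionless).
#' @export
cylinder_soft_count <- function(config, params = cv_params(), center = NULL) {
  tail_check(config)
  p <- params; p$cv_eq <- 1  # unused by the count itself
  res <- cpp_fullpath_cv(config$positions, role_codes(config$roles),
                         config$box, resolve_center(config, center),
                         unclass(p), FALSE)
  res$d
}

#' Convert a cylinder count to the defect coordinate
#'
#' `cv_cyl = 1 - d / cv_eq`: 0 for an intact equilibrated bilayer, 1 for an
#' empty cylinder (its upper limit), negative when the cylinder is overfilled.
#'
#' @param d Soft count from [cylinder_soft_count()].
#' @param cv_eq Equilibrium count (> 0).
#' @return Dimensionless defect coordinate.
#' @export
cv_cyl <- function(d, cv_eq) {
  if (!is.finite(cv_eq) || cv_eq <= 0) stop("`cv_eq` must be > 0")
  1 - d / cv_eq
}

#' Calibrate the equilibrium cylinder count from intact-bilayer frames
#'
#' Averages [cylinder_soft_count()] over a trajectory of pore-free frames
#' (the caller is responsible for supplying intact configurations) and
#' stores the result in the returned parameter set.
#'
#' @param frames A [particle_configuration()] or a list of them.
#' @param params A [cv_params()].
#' @param center Optional fixed cylinder axis.
#' @return `params` with `cv_eq` set; attributes `n_frames` and `sd` carry
#'   the calibration sample size and spread.
#' @export
calibrate_cv_eq <- function(frames, params = cv_params(), center = NULL) {
  if (inherits(frames, "particle_configuration")) frames <- list(frames)
  if (length(frames) == 0L) stop("calibration needs at least one frame")
  d <- vapply(frames, cylinder_soft_count, numeric(1),
              params = params, center = center)
  params$cv_eq <- mean(d)
  attr(params, "n_frames") <- length(d)
  attr(params, "sd") <- if (length(d) > 1) stats::sd(d) else 0
  params
}

#' Soft-minimum pore radius
#'
#' Smooth underestimating approximation of the minimum in-plane distance
#' from the pore axis to any tail bead, computed as a converging sum:
#' `r_soft = beta / log(sum_i exp(beta / d_i))`. Always `<=` the exact
#' minimum and converges to it as `beta` grows; distances are floored at
#' `dist_floor` to avoid overflow.
#'
#' @inheritParams cylinder_soft_count
#' @return Soft-minimum radius in nm.
#' @export
soft_min_radius <- function(config, params = cv_params(), center = NULL) {
  tail_check(config)
  p <- params; p$cv_eq <- 1
  res <- cpp_fullpath_cv(config$positions, role_codes(config$roles),
                         config$box, resolve_center(config, center),
                         unclass(p), FALSE)
  res$r_soft
}

#' Soft minimum of a set of distances
#'
#' The same converging-sum form used by [soft_min_radius()], exposed for
#' plain numeric inputs.
#'
#' @param d Positive distances (nm).
#' @param beta Sharpness (nm).
#' @param dist_floor Floor applied to each distance.
#' @return Soft minimum, always `<= min(d)`.
#' @export
soft_min <- function(d, beta = 50, dist_floor = 1e-3) {
  if (!length(d)) stop("empty distance set")
  e <- beta / pmax(d, dist_floor)
  m <- max(e)
  beta / (m + log(sum(exp(e - m))))
}

#' Evaluate the joint Full-Path collective variable
#'
#' Computes the defect coordinate `cv_cyl`, the pore-radius coordinate
#' `cv_radius = r_soft / r_unit`, the switching pair evaluated at
#' `cv_radius`, the blended value `s1 * cv_cyl + s2 * cv_radius`, and
#' (optionally) the exact analytic gradient of the value with respect to
#' every particle position. Head and water beads carry zero gradient, and
#' the z-component vanishes because the cylinder spans the box.
#'
#' @inheritParams cylinder_soft_count
#' @param gradient Logical; also return the per-particle gradient matrix.
#' @return An object of class `cv_value`: list with `value`, `cv_cyl`,
#'   `cv_radius`, `s1`, `s2`, `d`, `r_soft` and (optionally) `gradient`
#'   (n x 3, units 1/nm where applicable).
#' @export
fullpath_cv <- function(config, params, center = NULL, gradient = TRUE) {
  tail_check(config)
  if (!is.finite(params$cv_eq) || params$cv_eq <= 0)
    stop("`params$cv_eq` is not calibrated; run calibrate_cv_eq() first")
  res <- cpp_fullpath_cv(config$positions, role_codes(config$roles),
                         config$box, resolve_center(config, center),
                         unclass(params), gradient)
  structure(res, class = "cv_value")
}

#' @export
print.cv_value <- function(x, ...) {
  cat(sprintf("<cv_value> %.4f (cv_cyl %.4f, cv_radius %.4f, s1 %.3f)\n",
              x$value, x$cv_cyl, x$cv_radius, x$s1))
  invisible(x)
}

#' Evaluate the Full-Path CV along a trajectory
#'
#' @param frames List of [particle_configuration()] frames.
#' @param params Calibrated [cv_params()].
#' @param times Optional numeric times (ps); defaults to the frame index.
#' @param center Optional fixed cylinder axis.
#' @return A data.frame with columns `time`, `cv`, `cv_cyl`, `cv_radius`,
#'   `s1`, `s2`, ready for [write_series()].
#' @export
fullpath_cv_series <- function(frames, params, times = NULL, center = NULL) {
  if (inherits(frames, "particle_configuration")) frames <- list(frames)
  if (is.null(times)) times <- seq_along(frames) - 1
  rows <- lapply(frames, function(fr) {
    v <- fullpath_cv(fr, params, center = center, gradient = FALSE)
    c(cv = v$value, cv_cyl = v$cv_cyl, cv_radius = v$cv_radius,
      s1 = v$s1, s2 = v$s2)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(time = times), out)
}
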