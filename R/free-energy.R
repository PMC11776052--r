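#' Umbrella window container
#'
#' @param center Bias center (CV units).
#' @param kappa Harmonic force constant (kJ/mol per CV^2), > 0.
#' @param samples Numeric vector of sampled CV values.
#' @param temperature Temperature in K (default 310).
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, kappa, samples, temperature = 310) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("window samples must be finite")
  if (!is.finite(kappa) || kappa <= 0) stop("`kappa` must be > 0")
  structure(list(center = center, kappa = kappa, samples = samples,
                 temperature = temperature),
            class = "umbrella_window")
}

#' Evenly spaced umbrella window centers
#'
#' @param lo,hi Range ends (inclusive); `hi > lo`.
#' @param spacing Center spacing; must divide `hi - lo` evenly. Exactly one
#'   of `spacing`/`n` must be given.
#' @param n Number of centers.
#' @return Numeric vector of centers.
#' @export
make_window_centers <- function(lo, hi, spacing = NULL, n = NULL) {
  if (hi <= lo) stop("`hi` must exceed `lo`")
  if (is.null(spacing) == is.null(n))
    stop("give exactly one of `spacing` or `n`")
  if (!is.null(spacing)) {
    if (spacing <= 0) stop("`spacing` must be > 0")
    if (spacing > (hi - lo)) stop("`spacing` exceeds the requested range")
    steps <- (hi - lo) / spacing
    if (abs(steps - round(steps)) > 1e-8)
      stop("`spacing` does not evenly divide the range")
    seq(lo, hi, length.out = round(steps) + 1)
  } else {
    if (n < 2) stop("`n` must be >= 2")
    seq(lo, hi, length.out = n)
  }
}

#' Pick umbrella starting frames from a steered trajectory
#'
#' For each requested center, selects the frame whose recorded CV is nearest
#' (ties resolved to the earliest frame).
#'
#' @param frames List of configurations recorded along a steered pull.
#' @param cv Numeric vector of the recorded CV, one value per frame.
#' @param centers Window centers; each must lie inside the sampled CV range.
#' @return Integer vector of frame indices, one per center.
#' @export
seed_windows <- function(frames, cv, centers) {
  if (length(frames) != length(cv))
    stop("`frames` and `cv` must have equal length")
  rng <- range(cv)
  bad <- centers < rng[1] | centers > rng[2]
  if (any(bad))
    stop(sprintf("centers outside the sampled CV range [%.4f, %.4f]: %s",
                 rng[1], rng[2],
                 paste(signif(centers[bad], 4), collapse = ", ")))
  vapply(centers, function(ct) which.min(abs(cv - ct)), integer(1))
}

#' Free-energy profile container
#'
#' @param grid Bin centers (CV units).
#' @param G Free energy per bin (kJ/mol); `NA` on unsampled bins.
#' @param err Per-bin error (kJ/mol) or `NA`.
#' @param sampled Logical per-bin sampling flag.
#' @param kT Thermal energy used (kJ/mol).
#' @param meta Optional list of solver diagnostics.
#' @return An object of class `free_energy_profile`. `G` is shifted so the
#'   minimum over sampled bins is exactly 0 at the `reference` bin.
#' @export
free_energy_profile <- function(grid, G, err = rep(NA_real_, length(grid)),
                                sampled = is.finite(G), kT = NA_real_,
                                meta = list()) {
  stopifnot(length(grid) == length(G), length(err) == length(G))
  if (!any(sampled & is.finite(G)))
    stop("profile has no sampled bins")
  ref <- which.min(replace(G, !sampled, Inf))
  G <- G - G[ref]
  structure(list(grid = grid, G = G, err = err, sampled = sampled,
                 reference = ref, kT = kT, meta = meta),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("<free_energy_profile> %d bins on [%.4g, %.4g], %d sampled, max G %.3f kJ/mol\n",
              length(x$grid), min(x$grid), max(x$grid), sum(x$sampled),
              max(x$G[x$sampled])))
  invisible(x)
}

window_histograms <- function(windows, edges) {
  nb <- length(edges) - 1L
  t(vapply(windows, function(w) {
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    idx <- idx[idx >= 1L & idx <= nb]       # samples outside edges drop out
    as.numeric(tabulate(idx, nbins = nb))
  }, numeric(nb)))
}

#' Solve WHAM for a set of umbrella windows
#'
#' Standard self-consistent weighted-histogram unbiasing of overlapping
#' harmonic-window histograms, iterated on the window free energies until
#' the largest change drops below `tol`. Bias factors are bin-averaged by
#' Gauss-Legendre quadrature (a stiff bias varies substantially across a
#' bin); the profile is shifted so its sampled minimum is zero, and
#' unsampled bins are flagged (`NA`), never interpolated.
#'
#' @param windows List of [umbrella_window()] objects at one temperature.
#' @param n_bins Number of histogram bins over the sampled range
#'   (default 200).
#' @param edges Optional explicit bin edges overriding `n_bins`.
#' @param tol Convergence threshold on window free energies in kJ/mol
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 1e5).
#' @param overlap_warn Warn when an adjacent window pair shares less than
#'   this fraction of histogram weight (default 0.05).
#' @param min_count Bins with fewer pooled samples than this are flagged
#'   unsampled (default 20): below that the log-histogram estimate of G
#'   carries errors of several tenths of kT and would pollute downstream
#'   fits.
#' @return A [free_energy_profile()]; `meta` carries window free energies,
#'   iteration count and the worst adjacent overlap.
#' @export
wham_solve <- function(windows, n_bins = 200, edges = NULL, tol = 1e-8,
                       max_iter = 1e5, overlap_warn = 0.05, min_count = 20) {
  if (length(windows) < 1L) stop("need at least one window")
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9)
    stop("mixed-temperature windows are not supported")
  kT <- .kB * temps[1]
  allx <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(edges)) {
    rng <- range(allx)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(1e-6, abs(rng[1]) * 1e-6)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  B <- length(mids)
  K <- length(windows)
  cnt <- window_histograms(windows, edges)          # K x B
  N <- rowSums(cnt)
  num <- colSums(cnt)                                # pooled counts per bin

  # adjacent-overlap diagnostic on normalized histograms
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  overlaps <- rep(NA_real_, max(K - 1L, 0L))
  if (K >= 2L) {
    P <- cnt[ord, , drop = FALSE] / N[ord]
    for (i in seq_len(K - 1L))
      overlaps[i] <- sum(pmin(P[i, ], P[i + 1L, ]))
    if (min(overlaps) < overlap_warn)
      warning(sprintf("adjacent windows share only %.1f%% histogram weight (worst pair centered at %.4g / %.4g)",
                      100 * min(overlaps),
                      windows[[ord[which.min(overlaps)]]]$center,
                      windows[[ord[which.min(overlaps) + 1L]]]$center))
  }

  centers <- vapply(windows, `[[`, numeric(1), "center")
  kappas <- vapply(windows, `[[`, numeric(1), "kappa")
  # bin-averaged bias factors via 5-point Gauss-Legendre quadrature: with
  # stiff biases the factor varies strongly across a bin, and evaluating it
  # only at the bin center tilts the recovered profile
  gl_x <- c(-0.9061798459, -0.5384693101, 0, 0.5384693101, 0.9061798459)
  gl_w <- c(0.2369268851, 0.4786286705, 0.5688888889, 0.4786286705,
            0.2369268851) / 2
  hw <- diff(edges) / 2
  Bf <- matrix(0, K, B)
  for (q in seq_along(gl_x)) {
    xq <- mids + hw * gl_x[q]
    Uq <- 0.5 * outer(kappas, rep(1, B)) *
      (outer(rep(1, K), xq) - outer(centers, rep(1, B)))^2
    Bf <- Bf + gl_w[q] * exp(-Uq / kT)
  }

  z <- rep(1, K)
  f_old <- rep(0, K)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    denom <- as.numeric(crossprod(Bf, N / z))        # B
    p <- ifelse(num > 0, num / denom, 0)
    z_new <- as.numeric(Bf %*% p)
    z_new <- z_new / z_new[1]
    f_new <- -kT * log(z_new)
    if (max(abs(f_new - f_old)) < tol) { z <- z_new; converged <- TRUE; break }
    z <- z_new; f_old <- f_new
  }
  if (!converged) {
    worst <- if (all(is.na(overlaps))) NA_real_ else min(overlaps)
    stop(sprintf("WHAM did not converge in %d iterations (worst adjacent overlap %.2f%%); add windows or samples",
                 as.integer(max_iter), 100 * worst))
  }
  denom <- as.numeric(crossprod(Bf, N / z))
  p <- ifelse(num >= min_count, num / denom, NA_real_)
  G <- -kT * log(p)
  free_energy_profile(mids, G, sampled = num >= min_count, kT = kT,
                      meta = list(f_windows = -kT * log(z), n_iter = iter,
                                  overlaps = overlaps, edges = edges))
}

#' Quadratic (nucleation) fit of a free-energy profile
#'
#' Ordinary least squares of `G` against `CV^2` on the nucleation region
#' `CV <= cv_max`, returning the quadratic coefficient `k` and intercept
#' `c`.
#'
#' @param profile A [free_energy_profile()].
#' @param cv_max Upper CV bound of the fit range (default 0.5).
#' @return An object of class `quadratic_fit` with `k`, `c`, `rms` and
#'   `n_bins`.
#' @export
fit_quadratic <- function(profile, cv_max = 0.5) {
  keep <- profile$sampled & is.finite(profile$G) & profile$grid <= cv_max
  if (sum(keep) < 3L)
    stop("need at least 3 sampled bins with CV <= ", cv_max)
  x2 <- profile$grid[keep]^2
  fit <- stats::lm(profile$G[keep] ~ x2)
  structure(list(k = unname(coef(fit)[2]), c = unname(coef(fit)[1]),
                 rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_bins = sum(keep), cv_max = cv_max),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> k = %.4f kJ/mol/CV^2, c = %.4f kJ/mol (%d bins, CV <= %g)\n",
              x$k, x$c, x$n_bins, x$cv_max))
  invisible(x)
}

#' Line-tension fit of a free-energy profile
#'
#' Linear least squares of `G` against the CV on the pore-expansion region.
#' In `fullpath` mode the CV is a pore radius in units of `r_unit` and the
#' open-pore free energy follows `G(r) = 2 pi r gamma` for a single
#' circular rim, so `gamma = slope / (2 pi r_unit)`. In `rapid` mode the CV
#' is the rim-axis box length of a two-rim stripe and
#' `gamma = slope / n_rims`.
#'
#' @param profile A [free_energy_profile()].
#' @param mode `"fullpath"` or `"rapid"`.
#' @param cv_min Lower CV bound of the fit range (default 1.2 in fullpath
#'   mode, `-Inf` in rapid mode).
#' @param r_unit Pore radius unit in nm (fullpath mode).
#' @param n_rims Rim count (rapid mode, default 2).
#' @return A [line_tension_from_slope()] result; `slope_m` is the raw
#'   fitted slope in kJ mol^-1 per CV unit.
#' @export
fit_line_tension_profile <- function(profile, mode = c("fullpath", "rapid"),
                                     cv_min = NULL, r_unit = 1, n_rims = 2) {
  mode <- match.arg(mode)
  if (is.null(cv_min)) cv_min <- if (mode == "fullpath") 1.2 else -Inf
  keep <- profile$sampled & is.finite(profile$G) & profile$grid >= cv_min
  if (sum(keep) < 3L)
    stop("need at least 3 sampled bins with CV >= ", cv_min)
  fit <- stats::lm(profile$G[keep] ~ profile$grid[keep])
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope)) stop("non-finite fitted slope")
  if (mode == "fullpath")
    line_tension_from_slope(slope / (2 * pi * r_unit), n_rims = 1)
  else
    line_tension_from_slope(slope, n_rims = n_rims)
}

#' Halves-based error of a window estimator
#'
#' Splits every window's samples into first and second halves, applies the
#' estimator to each half, and reports half the absolute difference —
#' the convergence-style error used for both the nucleation coefficient and
#' the line tension.
#'
#' @param windows List of [umbrella_window()] objects, or a plain numeric
#'   vector when the estimator consumes samples directly.
#' @param estimator Function mapping window list (or vector) to a scalar.
#' @return `abs(estimate(first half) - estimate(second half)) / 2`.
#' @export
halves_error <- function(windows, estimator) {
  split_half <- function(x, part) {
    n <- length(x)
    if (n < 2L) stop("halves require at least two samples")
    if (part == 1L) x[seq_len(n %/% 2L)] else x[(n %/% 2L + 1L):n]
  }
  take <- function(part) {
    if (is.numeric(windows)) estimator(split_half(windows, part))
    else estimator(lapply(windows, function(w) {
      w$samples <- split_half(w$samples, part); w
    }))
  }
  abs(take(1L) - take(2L)) / 2
}

#' Bootstrap per-bin error of a WHAM profile
#'
#' Resamples each window's CV samples with replacement, re-solves WHAM per
#' replicate on the same bin grid (aligned at the full solve's reference
#' bin), and reports the per-bin standard deviation. With fewer than two
#' replicates the error is identically zero (degenerate case).
#'
#' @param windows List of [umbrella_window()] objects.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @param max_failures Replicates allowed to fail (non-overlap etc.) before
#'   the bootstrap aborts (default `n_boot %/% 10`).
#' @param ... Passed to [wham_solve()].
#' @return The full-data [free_energy_profile()] with `err` filled in.
#' @export
bootstrap_error <- function(windows, n_boot = 200, seed = 1L,
                            max_failures = NULL, ...) {
  if (length(windows) < 2L) stop("bootstrap needs at least two windows")
  if (is.null(max_failures)) max_failures <- n_boot %/% 10L
  full <- wham_solve(windows, ...)
  if (n_boot < 2L) {
    full$err <- rep(0, length(full$grid))
    return(full)
  }
  edges <- full$meta$edges
  ref <- full$reference
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(full$grid))
  fails <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      wb <- lapply(windows, function(w) {
        w$samples <- sample(w$samples, replace = TRUE); w
      })
      pb <- tryCatch(
        suppressWarnings(wham_solve(wb, edges = edges, ...)),
        error = function(e) NULL)
      if (is.null(pb)) {
        fails <- fails + 1L
        if (fails > max_failures)
          stop("too many bootstrap replicates failed (", fails, ")")
        next
      }
      g <- pb$G
      if (is.finite(g[ref])) g <- g - g[ref]
      reps[b, ] <- g
    }
  })
  full$err <- apply(reps, 2, function(col) {
    ok <- is.finite(col)
    if (sum(ok) > 1) stats::sd(col[ok]) else NA_real_
  })
  full
}

#' Block-wise WHAM profiles for convergence assessment
#'
#' Splits every window's series into `n_blocks` contiguous equal-length
#' blocks, solves WHAM per block, and reports the profiles together with
#' the maximum pairwise deviation (mean-aligned over commonly sampled
#' bins).
#'
#' @param windows List of [umbrella_window()] objects whose sample counts
#'   are divisible by `n_blocks`.
#' @param n_blocks Number of contiguous blocks.
#' @param ... Passed to [wham_solve()].
#' @return List with `profiles` (length `n_blocks`) and `max_deviation`
#'   (kJ/mol).
#' @export
block_convergence <- function(windows, n_blocks, ...) {
  if (n_blocks < 1L) stop("`n_blocks` must be >= 1")
  lens <- vapply(windows, function(w) length(w$samples), integer(1))
  if (any(lens == 0L)) stop("empty window series")
  if (any(lens %% n_blocks != 0L))
    stop("window series lengths must be divisible by `n_blocks` (equal blocks)")
  full <- wham_solve(windows, ...)
  edges <- full$meta$edges
  profiles <- lapply(seq_len(n_blocks), function(b) {
    wb <- lapply(windows, function(w) {
      m <- length(w$samples) %/% n_blocks
      w$samples <- w$samples[((b - 1L) * m + 1L):(b * m)]
      w
    })
    suppressWarnings(wham_solve(wb, edges = edges, ...))
  })
  maxdev <- 0
  if (n_blocks >= 2L) {
    for (a in seq_len(n_blocks - 1L)) for (b in (a + 1L):n_blocks) {
      pa <- profiles[[a]]; pb <- profiles[[b]]
      ok <- pa$sampled & pb$sampled
      if (sum(ok) >= 2L) {
        d <- pa$G[ok] - pb$G[ok]
        maxdev <- max(maxdev, max(abs(d - mean(d))))
      }
    }
  }
  list(profiles = profiles, max_deviation = maxdev)
}

#' Compare a profile against a reference curve
#'
#' Root-mean-square deviation over sampled bins after removing the additive
#' constant (free energies are defined up to one), i.e. after aligning
#' means over the compared support.
#'
#' @param profile A [free_energy_profile()].
#' @param g_fun Function of the CV returning reference free energies
#'   (kJ/mol), or a numeric vector on `profile$grid`.
#' @return RMS deviation in kJ/mol.
#' @export
profile_rms <- function(profile, g_fun) {
  gref <- if (is.function(g_fun)) g_fun(profile$grid) else as.numeric(g_fun)
  ok <- profile$sampled & is.finite(profile$G) & is.finite(gref)
  d <- profile$G[ok] - gref[ok]
  sqrt(mean((d - mean(d))^2))
}

#' Draw CV samples from a biased Boltzmann density
#'
#' Inverse-CDF sampling of `exp(-(G(x) + kappa/2 (x - center)^2) / kT)` on
#' a fine grid — an exact generator for validating the WHAM solver against
#' an analytic free-energy curve.
#'
#' @param g_fun Function returning G(x) in kJ/mol.
#' @param center,kappa Harmonic bias parameters.
#' @param n Number of samples.
#' @param temperature Temperature in K.
#' @param lo,hi Support of the density.
#' @param n_grid Grid resolution.
#' @return Numeric vector of `n` samples (uses the current RNG stream;
#'   seed with [set.seed()] or `with_seed`).
#' @export
sample_biased_boltzmann <- function(g_fun, center, kappa, n,
                                    temperature = 310, lo = -2, hi = 2,
                                    n_grid = 20001L) {
  kT <- .kB * temperature
  x <- seq(lo, hi, length.out = n_grid)
  logw <- -(g_fun(x) + 0.5 * kappa * (x - center)^2) / kT
  w <- exp(logw - max(logw))
  cdf <- cumsum(w) - w / 2
  cdf <- cdf / sum(w)
  keep <- !duplicated(cdf)
  stats::approx(cdf[keep], x[keep], xout = stats::runif(n), rule = 2)$y
}
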