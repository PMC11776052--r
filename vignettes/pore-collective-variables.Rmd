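---
title: "Collective variables and free-energy estimation for membrane pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective variables and free-energy estimation for membrane pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porecv)
```

## The problem

Pore formation in lipid bilayers proceeds in two regimes: nucleation of a
hydrophilic defect, whose free energy grows roughly quadratically with defect
size, and expansion of an open pore, whose free energy grows linearly with
the rim length at a rate set by the line tension $\gamma$. Biasing either
regime in molecular simulation requires a collective variable (CV) — a
smooth, differentiable scalar function of particle coordinates — that tracks
the whole path from intact membrane to open pore without hysteresis.

`porecv` implements two such CVs and everything needed to exercise them end
to end on synthetic systems:

* a **joint "Full-Path" CV** blending a cylinder-density defect coordinate
  with a soft-minimum pore-radius coordinate, with exact analytic gradients;
* a **"Rapid" box-length CV** for lipid stripes (ribbons with two free
  edges), which models a pore of infinite radius and yields the line tension
  from the slope of a linear free-energy profile.

Everything runs on a deliberately minimal bead-lipid model, so the full
pipeline — steered pulls, umbrella windows, WHAM, fits, error bars — is
testable on a laptop. None of the machinery is tied to the toy model: any
code that produces particle configurations or CV time series in the
supported formats can feed it.

## The Full-Path CV

For a configuration with tail beads $i$ at in-plane distances $\rho_i$ from
the pore axis (the box xy-center by default), the two components are:

**Defect coordinate.** A virtual cylinder of radius $R_\mathrm{cyl}$
(default 1.2 nm) spans the box along the membrane normal. The soft count of
tail beads inside it is
$d = \sum_i w(\rho_i)$, with a smoothly decaying rational membership
$$
w(\rho) = \frac{1 - (\rho/R_\mathrm{cyl})^n}{1 - (\rho/R_\mathrm{cyl})^m},
\qquad (n, m) = (6, 12)\ \text{by default},
$$
which equals 1 on the axis and $n/m$ at $\rho = R_\mathrm{cyl}$ (for
$m = 2n$ it reduces exactly to $1/(1 + x^n)$). The defect coordinate is
$\mathrm{CV}_\mathrm{cyl} = 1 - d/\mathrm{CV}_\mathrm{eq}$, where
$\mathrm{CV}_\mathrm{eq}$ is calibrated as the time-averaged count in an
intact, equilibrated bilayer (`calibrate_cv_eq()`). It reads 0 for an intact
membrane, 1 for an empty cylinder, and may go slightly negative for an
overfilled one — umbrella grids therefore start just below zero.

**Pore-radius coordinate.** The smallest in-plane distance from the axis to
any tail bead, made smooth by a converging-sum soft minimum
$$
r_\mathrm{soft} = \frac{\beta}{\ln \sum_i e^{\beta / d_i}},
$$
which always underestimates the true minimum and converges to it as
$\beta \to \infty$ (default $\beta = 50$ nm; distances floored at
$10^{-3}$ nm to avoid overflow). Dimensionless:
$\mathrm{CV}_\mathrm{radius} = r_\mathrm{soft} / r_\mathrm{unit}$ with
$r_\mathrm{unit} = 1$ nm.

**The blend.** A complementary logistic switching pair
$$
s_1(x) = \frac{1}{1 + e^{\alpha (x - \mathrm{CV}_0)}},\qquad s_2 = 1 - s_1,
$$
with $\mathrm{CV}_0 = 0.95$ and $\alpha = 20$, forms the joint value
$$
\mathrm{CV} = s_1\,\mathrm{CV}_\mathrm{cyl} + s_2\,\mathrm{CV}_\mathrm{radius}.
$$
$\mathrm{CV}_0$ must sit strictly between 0.5 and 1: high enough that the
defect coordinate carries the nucleation regime, low enough that the blend
hands over before the radius coordinate saturates.

**Design choices made here.** The verbal contract of the switching pair —
complementary, smooth, intersecting at $\mathrm{CV}_0$, rate $\alpha$ —
does not pin down a functional form; the logistic pair is the simplest one
satisfying all of it. The argument fed to the switch is
$\mathrm{CV}_\mathrm{radius}$: below threshold the joint CV reduces to the
defect coordinate (intact membranes have small nearest-tail distances, so
$s_1 \approx 1$), and once the cavity radius crosses $\mathrm{CV}_0$ the
blend hands over permanently to the radius coordinate, so an open pore of
radius $r$ reads $\mathrm{CV} \approx r / r_\mathrm{unit}$. Feeding the
defect coordinate to the switch instead was tried and rejected: because
$s_1(\mathrm{CV}_\mathrm{cyl} \approx 1)$ never falls below $\approx 0.27$,
the joint value would saturate visibly below the true pore radius for every
open-pore geometry. The cylinder axis is treated as a fixed reference point
(the box xy-center unless overridden): systems are built centered, a bias
localizes the pore at the cylinder anyway, and a fixed axis keeps the
analytic gradient exact, with head and water beads carrying exactly zero
gradient. A center-of-geometry axis was tried and rejected — with a pore
present, the lipid COG is displaced from the pore axis by the surrounding
lattice and biases the radius coordinate low.

The analytic per-particle gradient of the joint value (including the
switch-argument coupling term
$(\mathrm{CV}_\mathrm{cyl} - \mathrm{CV}_\mathrm{radius})\, s_1'$) is
returned by `fullpath_cv()` and verified against central finite differences
to $10^{-5}$ in the test suite.

```{r cv-example}
spec <- geometry_spec(n_lipids = 128, area_per_lipid = 0.64, seed = 1)
flat <- build_flat_bilayer(spec)
params <- calibrate_cv_eq(flat, cv_params())
fullpath_cv(flat, params, gradient = FALSE)$value
spec$pore_radius <- 1.5
fullpath_cv(build_pore_bilayer(spec), params, gradient = FALSE)$value
```

## The Rapid CV and line tension

A lipid stripe is a bilayer ribbon, periodic along one axis (the rim axis,
y) and finite along another (z), terminated by two head-capped rims; the
membrane normal (x, default box edge 8.5 nm) completes the frame. Because
the rims are straight and maintained by periodicity, stretching the box
along the rim axis lengthens both rims at constant lipid number, and the
free energy grows linearly: $\mathrm{d}G/\mathrm{d}L = 2\gamma$ in
kJ mol$^{-1}$ nm$^{-1}$. The CV is simply the box edge along the rim axis
(`rim_length_cv()`), biased harmonically (default
$\kappa = 5000$ kJ mol$^{-1}$ nm$^{-2}$) over a ladder of windows (21
evenly spaced windows spanning 6–6.6 nm in the reference protocol; the toy
pipeline defaults to 11 windows over $L_0 \pm 0.3$ nm). A flat-bottom
restraint ($k_\mathrm{fb} = 1000$ kJ mol$^{-1}$ nm$^{-2}$, half-width
2.5 nm) on head beads along the normal, relative to the stripe's center of
mass, prevents the stripe from drifting or interacting with its periodic
image.

The fitted slope $m$ of $G(L)$ gives the line tension per rim,
$\gamma = m / 2$, reported both in kJ mol$^{-1}$ nm$^{-1}$ and per
molecule in pN (1 kJ mol$^{-1}$ nm$^{-1}$ = 1.66054 pN, i.e. division by
the Avogadro constant).

## Pore state and lifetime

Spontaneous pore closure is followed with a slice-occupancy observable: the
membrane core interval $[-2.125, 2.125]$ nm around the lipid center of
geometry is split into 17 slices of 0.25 nm. Each water molecule
contributes a peak-normalized Gaussian weight (bandwidth 0.1 nm, truncated
at the slice boundaries) to its slice, so a molecule at a slice center
counts as exactly one — which makes the "fewer than one molecule" dryness
threshold meaningful; the weighted count is used rather than the raw count
so the observable degrades smoothly as waters leave a slice. A Heaviside
step (boundary counted as wet) and an average give the pore state
$s \in [0, 1]$: 1 for a continuous transmembrane water column, dropping as
the column breaks. The closure curve is fitted with
$$
s(t) = A_0 \left(1 - \tanh(A_1 (t - A_2))\right),
$$
the minimal three-parameter sigmoidal decay whose inflection $A_2$ is the
pore lifetime. ($A_2$ is initialized at the first time $s$ drops below
half its initial plateau; the fit uses Levenberg–Marquardt least squares.)
The companion observable `distal_tail_density()` — the core-region number
density of terminal tail beads — is the structural quantity that tracks
how easily a membrane reseals.

## Umbrella sampling and WHAM

`wham_solve()` implements standard self-consistent histogram unbiasing in
the window free energies, iterated to $10^{-8}$ kJ/mol with bias factors
evaluated at bin centers (default 200 bins over the sampled range).
Unsampled bins are flagged, never interpolated; the profile is shifted so
its sampled minimum is exactly zero. Adjacent windows sharing less than 5%
histogram weight trigger a warning, and non-convergence reports the worst
gap. Error estimation follows two routes: *halves errors* (half the
absolute difference between estimates from the first and second halves of
each window's production samples — used for the nucleation coefficient $k$
and for $\gamma$) and a *bootstrap* over samples within windows (default
200 replicates) for per-bin profile errors. Halves errors are
convergence-style diagnostics of a single run; they underestimate the
replicate-to-replicate spread of fitted coefficients, so comparisons
across independent runs should treat them as lower bounds. `block_convergence()` overlays
profiles from contiguous sample blocks as a convergence diagnostic.

Fits: `fit_quadratic()` regresses $G$ on $\mathrm{CV}^2$ over the
nucleation region $\mathrm{CV} \le 0.5$ (reading the garbled published fit
description as a regression of $G$ on the squared CV, which is the only
reading consistent with the stated symbols), and
`fit_line_tension_profile()` fits the expansion region
($\mathrm{CV} \ge 1.2$ in full-path mode, where $G(r) = 2\pi r \gamma$ for
a single circular rim; the whole range in rapid mode, two rims).

The solver is validated against an exact generator:
`sample_biased_boltzmann()` draws inverse-CDF samples from the analytic
biased densities of a known double-well $G(x) = 10\,(x^2 - 1)^2$ kJ/mol.
With $\kappa = 5000$ and $n = 5000$ per window the stiff-spring width is
$\sigma = \sqrt{k_B T / \kappa} \approx 0.023$ and adjacent-window overlap
controls the error with which WHAM stitches neighboring windows together;
these per-link errors accumulate as a random walk along the ladder. The 20
validation windows are therefore spaced $\approx 1.65\sigma$ apart
(centers $\pm 0.36$), which an error-budget decomposition of the window
free energies shows keeps the accumulated stitching error comfortably
inside the target; the recovered profile then agrees with the analytic
curve to an RMS below 0.3 kJ/mol. Bins holding fewer than `min_count`
pooled samples (default 20) are flagged unsampled rather than reported: a
log-histogram estimate from a handful of counts carries errors of several
tenths of kT and would otherwise dominate both the validation RMS and any
fit touching the range edges.

## The toy engine and what it does (not) show

The synthetic systems are three-bead lipids — head, tail, terminal tail,
0.95 nm apart — with water as inert marker particles (density default
8 nm$^{-3}$; observables depend on occupancy, not density). The dynamics
engine is BAOAB Langevin integration (310 K, bead mass 100 amu, default
step 0.01–0.02 ps, friction 1 ps$^{-1}$) of a Cooke-style implicit-solvent
force field: WCA cores (1 nm tail beads, heads 5% smaller), FENE bonds, a
head-to-terminal straightening spring, and a broadened tail–tail
attraction with a smooth quartic shoulder (depth 2.4 kJ/mol by default, i.e. $k_B T / \varepsilon \approx
1.07$ at 310 K — inside the fluid-bilayer regime of this model class;
range 1.6 nm). The unit mapping is direct (nm, kJ/mol, ps), so line
tensions and free energies come out in real units, and all forces are exact
negative gradients (finite-difference-checked per term).

Biases enter the integrator by chain rule from the CV gradients. The
rim-length CV is biased through an overdamped piston on the y box edge:
every 10 steps the generalized force $-\partial U/\partial L_y$ (central
finite difference of the potential under affine rescaling) plus the
harmonic bias force moves the edge, capped at 0.5% per move, followed by
affine rescaling of the y coordinates. The stripe-width (z) direction needs
no barostat: the rims are free edges and the width relaxes on its own — a
simplification relative to semi-isotropic pressure coupling that costs
nothing for this geometry. End-to-end pipelines pre-equilibrate briefly and
walk the window ladder middle-out, chaining each window from its
neighbor's final state; this matters at stronger cohesion, where starting
a compressed window directly from the lattice can overstretch bonds.

Seeding: one master seed; stage $i$ of a pipeline uses `seed + i`, so runs
are bitwise reproducible and windows are statistically independent. The
pair interactions run over a Verlet neighbor list (0.4 nm skin, rebuilt
once any bead has moved half a skin), which is what makes the end-to-end
umbrella pipelines fast enough to test routinely.

Window length matters for the hysteresis check: with windows an order of
magnitude shorter than the defaults, the forward- and reverse-seeded
nucleation coefficients disagree well beyond their halves errors — an
equilibration artifact of windows seeded from freshly pulled frames, not
intrinsic CV hysteresis — and the disagreement collapses into the error
band once each window runs 40 000 steps with the first 75% discarded.
This mirrors the reference analysis policy of discarding most of each
window before measuring.

**What the synthetic systems do not emulate:** chemical detail
(head-group electrostatics, ions, solvent structure), realistic kinetics,
or quantitative line tensions of any real lipid. Passing tests therefore
demonstrate that the CV definitions, gradients, reweighting and fits are
mathematically correct and that the pipeline is self-consistent on a
membrane-like system — not that the toy model reproduces experimental
membrane energetics.

## Builder geometry conventions

Bilayers: leaflet lattices (near-square factorization of the leaflet count;
default area per lipid 1.1 nm$^2$, the toy model's equilibrium packing —
tighter values like 0.64 nm$^2$ are fine for pure-geometry fixtures),
heads outward, membrane centered at the box mid-plane, bulk water slabs
above and below. Pores: lipids inside a circular area are removed from the
flat lattice and re-placed on a half-torus rim, heads lining the
water-facing surface; `pore_radius` means the radius of the *tail-free*
cavity, with the innermost tail ring sitting 0.15 nm outside it — chosen
from the soft-minimum error analysis (underestimate factor
$d/(1 + d \ln n_\mathrm{eff} / \beta)$) so that the joint CV reads back the
nominal radius to within a few percent. The water column (radius
`pore_radius` − 0.4 nm, present when positive) places layers on multiples
of 0.125 nm from the mid-plane so every 0.25 nm slice center coincides
with a layer: pores of radius ≥ 0.5 nm are wet in every core slice, and
near-zero pores have no column at all. Stripes: the outermost lattice rows
become two hemicylindrical head-capped rims (cap geometry is a modeling
choice — the reference protocol does not specify one), with a periodic-image
gap ≥ 2 nm enforced along the finite axis.

## Numerical details and limitations

* WHAM iterates in linear space with per-iteration normalization on the
  first window; bias factors below double-precision underflow drop out
  harmlessly. Degenerate all-equal samples expand to a token bin range.
* The soft minimum floors distances at $10^{-3}$ nm; beads essentially on
  the axis contribute a constant and zero gradient.
* `fit_pore_lifetime()` refuses series that never drop below 60% of their
  initial plateau (no closure to date) and series with fewer than 10
  points.
* Bootstrap replicates that fail to converge are skipped up to a cap
  (default `n_boot/10`); a single replicate yields zero errors by
  definition.
* The scaled-down end-to-end runs (60 lipids, 11–12 windows,
  15 000–30 000 steps per window) are sized for a single CPU; their
  outputs are stochastic with seed-level reproducibility. Hysteresis is
  assessed by comparing the forward- and reverse-seeded nucleation
  coefficients within their combined halves errors, mirroring the
  halves-based error convention used for all fitted coefficients.
* The toy engine supports only orthorhombic boxes and equal bead masses;
  there is no electrostatics, no explicit solvent, and no replica exchange.
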