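#' Geometry specification for synthetic membrane builders
#'
#' Describes the membrane-like bead systems the package can generate: flat
#' bilayers, bilayers with a cylindrical pore plus water column, and lipid
#' stripes (ribbons) with two rims. Lipids are three beads (head H, tail T,
#' terminal tail TT) stacked along the membrane normal.
#'
#' @param n_lipids Even total lipid count (split equally between leaflets).
#' @param area_per_lipid Lateral area per lipid in nm^2. Default 1.1, the
#'   equilibrium packing of the toy bead model (see [toy_forcefield()]).
#' @param leaflet_separation Gap in nm between the two terminal-tail planes.
#' @param pore_radius Radius in nm of the tail-free cylindrical cavity
#'   (0 = no pore). The nominal radius is measured in the tail metric: the
#'   innermost tail beads sit just outside it while head beads line the rim.
#' @param stripe Logical; build a ribbon with two rims instead of a bilayer.
#' @param water_density Water particles per nm^3 used for bulk slabs and the
#'   pore water column. Default 8 (visual plausibility; observables depend on
#'   occupancy, not exact density).
#' @param seed Integer seed; builders are deterministic given the spec.
#' @param bead_spacing Distance in nm between consecutive beads of a lipid.
#' @param normal_edge Box edge along the stripe normal in nm (default 8.5).
#' @param rim_gap Periodic-image gap in nm between the two stripe rims
#'   (must be >= 2).
#' @param water_slab Thickness in nm of the bulk water slabs on either side
#'   of a bilayer.
#'
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(n_lipids, area_per_lipid = 1.1,
                          leaflet_separation = 0.8, pore_radius = 0,
                          stripe = FALSE, water_density = 8, seed = 1L,
                          bead_spacing = 0.95, normal_edge = 8.5,
                          rim_gap = 3.0, water_slab = 1.5) {
  spec <- structure(
    list(n_lipids = as.integer(n_lipids), area_per_lipid = area_per_lipid,
         leaflet_separation = leaflet_separation, pore_radius = pore_radius,
         stripe = isTRUE(stripe), water_density = water_density,
         seed = as.integer(seed), bead_spacing = bead_spacing,
         normal_edge = normal_edge, rim_gap = rim_gap,
         water_slab = water_slab),
    class = "geometry_spec")
  if (spec$n_lipids < 2L || spec$n_lipids %% 2L != 0L)
    stop("`n_lipids` must be even and >= 2 (equal leaflets)")
  if (spec$pore_radius < 0) stop("`pore_radius` must be >= 0")
  if (spec$water_density < 0) stop("`water_density` must be >= 0")
  if (spec$area_per_lipid <= 0 || spec$bead_spacing <= 0 ||
      spec$leaflet_separation <= 0 || spec$normal_edge <= 0 ||
      spec$water_slab < 0)
    stop("geometric dimensions must be positive")
  spec
}

# membrane half-thickness: terminal-tail plane at g/2, head plane at g/2 + 2b
half_thickness <- function(spec) {
  spec$leaflet_separation / 2 + 2 * spec$bead_spacing
}

# radial clearance of the innermost rim tail beads above the nominal pore
# radius; chosen so the soft-minimum pore radius (beta = 50) reads back the
# nominal radius to within a few percent
.rim_tail_clearance <- 0.15

# near-square factorization of a leaflet count; errors when only very
# elongated grids exist
leaflet_grid <- function(n_per, max_aspect = 2.5) {
  nx <- floor(sqrt(n_per))
  while (nx >= 1L && n_per %% nx != 0L) nx <- nx - 1L
  ny <- n_per %/% nx
  if (ny / nx > max_aspect)
    stop(sprintf("n_lipids = %d does not factor into a rectangular leaflet grid",
                 2L * n_per))
  c(nx, ny)
}

# 3-bead lipid stack along +/- normal; returns 3x3 matrix of bead offsets
# (rows H, T, TT) along the axis unit vector
lipid_stack <- function(spec, sign) {
  h <- half_thickness(spec)
  b <- spec$bead_spacing
  sign * c(h, h - b, h - 2 * b)
}

# water lattice filling an axis-aligned slab, with small seeded jitter
water_slab_lattice <- function(lo, hi, density) {
  vol <- prod(hi - lo)
  n <- round(density * vol)
  if (n < 1) return(matrix(numeric(0), ncol = 3))
  s <- (vol / n)^(1 / 3)
  dims <- pmax(1L, round((hi - lo) / s))
  while (prod(dims) < n) dims[which.min(dims)] <- dims[which.min(dims)] + 1L
  g <- as.matrix(expand.grid(
    x = (seq_len(dims[1]) - 0.5) / dims[1],
    y = (seq_len(dims[2]) - 0.5) / dims[2],
    z = (seq_len(dims[3]) - 0.5) / dims[3]))
  g <- g[seq_len(n), , drop = FALSE]
  g <- sweep(sweep(g, 2, hi - lo, "*"), 2, lo, "+")
  g + matrix(runif(3 * n, -0.05, 0.05) * s, ncol = 3)
}

assemble_configuration <- function(lip_pos, n_lipids, wat_pos, box,
                                   periodic = c(TRUE, TRUE, TRUE)) {
  n_w <- nrow(wat_pos)
  positions <- rbind(lip_pos, wat_pos)
  roles <- c(rep(c("head", "tail", "terminal_tail"), n_lipids),
             rep("water", n_w))
  lipid_ids <- c(rep(seq_len(n_lipids), each = 3L), rep(NA_integer_, n_w))
  wrap_configuration(particle_configuration(positions, roles, lipid_ids,
                                            box, periodic))
}

#' Build a flat bilayer
#'
#' Places `n_lipids/2` lipids per leaflet on a rectangular lattice with heads
#' pointing outward along z and the membrane centered at the box mid-plane;
#' bulk water fills slabs above and below at `water_density`.
#'
#' @param spec A [geometry_spec()] with `stripe = FALSE` and `pore_radius = 0`.
#' @return A [particle_configuration()].
#' @export
build_flat_bilayer <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$stripe || spec$pore_radius != 0)
    stop("flat-bilayer spec must have stripe = FALSE and pore_radius = 0")
  with_seed(spec$seed, build_flat_bilayer_impl(spec))
}

build_flat_bilayer_impl <- function(spec) {
  n_per <- spec$n_lipids %/% 2L
  dims <- leaflet_grid(n_per)
  a <- sqrt(spec$area_per_lipid)
  box <- c(dims[1] * a, dims[2] * a, 2 * (half_thickness(spec) + spec$water_slab))
  z_mid <- box[3] / 2
  site <- as.matrix(expand.grid(x = (seq_len(dims[1]) - 0.5) * a,
                                y = (seq_len(dims[2]) - 0.5) * a))
  lip_pos <- matrix(0, nrow = 3L * spec$n_lipids, ncol = 3)
  row <- 1L
  for (leaflet in c(+1, -1)) {
    off <- if (leaflet > 0) c(0, 0) else c(a / 2, a / 2)  # stagger leaflets
    zs <- z_mid + lipid_stack(spec, leaflet)
    for (i in seq_len(n_per)) {
      xy <- site[i, ] + off
      lip_pos[row:(row + 2L), ] <- cbind(rep(xy[1], 3), rep(xy[2], 3), zs)
      row <- row + 3L
    }
  }
  h <- half_thickness(spec)
  wat <- rbind(
    water_slab_lattice(c(0, 0, 0), c(box[1], box[2], z_mid - h - 0.5),
                       spec$water_density),
    water_slab_lattice(c(0, 0, z_mid + h + 0.5), box, spec$water_density))
  assemble_configuration(lip_pos, spec$n_lipids, wat, box)
}

#' Build a bilayer with a cylindrical pore and water column
#'
#' Starts from the flat-bilayer lattice, removes every lipid whose site falls
#' inside the rim annulus, and re-places exactly that many lipids on a
#' half-torus rim: heads line the water-facing surface while tail beads stay
#' outside the nominal `pore_radius` (tail-metric cavity). A water column
#' fills the channel so that, for `pore_radius >= 0.5` nm, every 0.25 nm
#' slice through the membrane core is occupied.
#'
#' @param spec A [geometry_spec()] with `pore_radius > 0`.
#' @return A [particle_configuration()].
#' @export
build_pore_bilayer <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$pore_radius <= 0) stop("`pore_radius` must be > 0")
  with_seed(spec$seed, build_pore_bilayer_impl(spec))
}

build_pore_bilayer_impl <- function(spec) {
  flat <- build_flat_bilayer_impl(spec)
  box <- flat$box
  if (spec$pore_radius > min(box[1:2]) / 2)
    stop("`pore_radius` exceeds half the smallest lateral box edge")
  z_mid <- box[3] / 2
  h <- half_thickness(spec)
  b <- spec$bead_spacing
  rp <- spec$pore_radius
  # tube-center circle of the half-torus rim: innermost tail ring (tube-radial
  # coordinate h - b at theta = 0) lands at rp + clearance
  rho_c <- rp + .rim_tail_clearance + h - b

  keep_w <- flat$roles == "water"
  head_rows <- which(flat$roles == "head")
  ctr <- box[1:2] / 2
  head_rho <- sqrt((flat$positions[head_rows, 1] - ctr[1])^2 +
                   (flat$positions[head_rows, 2] - ctr[2])^2)
  drop_ids <- flat$lipid_ids[head_rows][head_rho < rho_c]
  n_rim <- length(drop_ids)
  if (n_rim == 0L)
    stop("pore does not intersect the lipid lattice; enlarge `pore_radius`")
  keep_lip <- !(flat$lipid_ids %in% drop_ids) & !keep_w
  n_flat <- sum(keep_lip) %/% 3L

  # distribute the removed lipids over half-torus rows, counts proportional to
  # the tail-ring circumference of each row
  n_rows <- min(5L, n_rim)
  theta <- -pi / 2 + pi * (seq_len(n_rows) - 0.5) / n_rows
  ring_rho <- pmax(rho_c - (h - b) * cos(theta), 0.1)
  alloc <- largest_remainder(n_rim * ring_rho / sum(ring_rho), n_rim)
  rim_pos <- matrix(0, nrow = 3L * n_rim, ncol = 3)
  row <- 1L
  for (j in seq_len(n_rows)) {
    if (alloc[j] == 0L) next
    phis <- 2 * pi * (seq_len(alloc[j]) - 0.5) / alloc[j] + theta[j]  # stagger rows
    for (phi in phis) {
      tau <- c(h, h - b, h - 2 * b)              # H, T, TT tube-radial coords
      rho <- pmax(rho_c - tau * cos(theta[j]), 0.02)
      zz <- z_mid + tau * sin(theta[j])
      rim_pos[row:(row + 2L), ] <- cbind(ctr[1] + rho * cos(phi),
                                         ctr[2] + rho * sin(phi), zz)
      row <- row + 3L
    }
  }

  n_lip <- n_flat + n_rim
  lip_pos <- rbind(flat$positions[keep_lip, , drop = FALSE], rim_pos)

  # water: bulk slabs from the flat build plus a channel column whose layers
  # sit on multiples of 0.125 nm from the mid-plane, so every 0.25 nm slice
  # center coincides with a layer
  wat <- flat$positions[keep_w, , drop = FALSE]
  r_w <- rp - 0.4
  if (r_w > 0.05) {
    k_max <- ceiling((h + 0.5) / 0.125)
    col <- do.call(rbind, lapply(-k_max:k_max, function(k) {
      n_l <- max(1L, round(spec$water_density * pi * r_w^2 * 0.125))
      i <- seq_len(n_l)
      rr <- if (n_l == 1L) 0 else r_w * sqrt((i - 1) / n_l)
      ang <- i * 2.399963 + k  # golden-angle spiral, rotated per layer
      cbind(ctr[1] + rr * cos(ang), ctr[2] + rr * sin(ang),
            z_mid + k * 0.125)
    }))
    wat <- rbind(wat, col)
  }
  assemble_configuration(lip_pos, n_lip, wat, box)
}

# apportion n into integer counts matching fractional shares
largest_remainder <- function(shares, n) {
  raw <- shares / sum(shares) * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Build a lipid stripe (ribbon with two rims)
#'
#' A bilayer ribbon with membrane normal along x, periodic (continuous) along
#' y, and finite along z where two hemicylindrical head-capped rims terminate
#' it. The box edge along the normal is `normal_edge` (default 8.5 nm) and
#' the periodic-image gap between the rims is `rim_gap` (>= 2 nm).
#'
#' @param spec A [geometry_spec()] with `stripe = TRUE`.
#' @return A [particle_configuration()]; only y (the rim axis) and x are
#'   periodic in spirit, but the box is stored fully periodic with the rim
#'   gap guaranteeing image separation along z.
#' @export
build_stripe <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (!spec$stripe) stop("stripe spec must have stripe = TRUE")
  if (spec$rim_gap < 2)
    stop("`rim_gap` must be >= 2 nm to keep periodic rim images apart")
  with_seed(spec$seed, build_stripe_impl(spec))
}

build_stripe_impl <- function(spec) {
  n_per <- spec$n_lipids %/% 2L
  dims <- leaflet_grid(n_per)          # dims[2] rows along y (periodic axis)
  n_z <- dims[1]; n_y <- dims[2]
  if (n_z < 3L)
    stop("stripe needs at least 3 lattice rows across its width")
  a <- sqrt(spec$area_per_lipid)
  h <- half_thickness(spec)
  b <- spec$bead_spacing
  theta_cap <- 40 * pi / 180
  n_zf <- n_z - 2L                     # flat rows; outer rows become the caps
  extent <- n_zf * a + 2 * (a / 2 + h * cos(theta_cap) + 0.5)
  box <- c(spec$normal_edge, n_y * a, extent + spec$rim_gap)
  x_mid <- box[1] / 2
  z_mid <- box[3] / 2
  ys <- (seq_len(n_y) - 0.5) * a

  lip <- list(); li <- 0L
  add_lipid <- function(pos3) { li <<- li + 1L; lip[[li]] <<- pos3 }
  # flat ribbon rows
  for (leaflet in c(+1, -1)) {
    xs <- x_mid + lipid_stack(spec, leaflet)
    yoff <- if (leaflet > 0) 0 else a / 2
    for (j in seq_len(n_zf)) {
      z <- z_mid + (j - (n_zf + 1) / 2) * a
      for (y in ys + yoff)
        add_lipid(cbind(xs, y, z))
    }
  }
  # hemicylindrical caps: one row per leaflet per side, bent outward
  z_cap <- z_mid + c(-1, +1) * (n_zf * a / 2 + a / 2)
  for (side in 1:2) {
    dirz <- c(-1, +1)[side]
    for (leaflet in c(+1, -1)) {
      th <- leaflet * theta_cap
      tau <- c(h, h - b, h - 2 * b)
      xs <- x_mid + tau * sin(th)
      zs <- z_cap[side] + dirz * tau * cos(theta_cap)
      yoff <- if (leaflet > 0) 0 else a / 2
      for (y in ys + yoff)
        add_lipid(cbind(xs, y, zs))
    }
  }
  lip_pos <- do.call(rbind, lip)
  n_lip <- li
  stopifnot(n_lip == spec$n_lipids)

  wat <- if (spec$water_density > 0) rbind(
    water_slab_lattice(c(0, 0, 0), c(x_mid - h - 0.5, box[2], box[3]),
                       spec$water_density),
    water_slab_lattice(c(x_mid + h + 0.5, 0, 0), box, spec$water_density))
  else matrix(numeric(0), ncol = 3)
  assemble_configuration(lip_pos, n_lip, wat, box)
}
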