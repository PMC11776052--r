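#' Particle roles used by all builders and observables
#'
#' Every particle carries one of four roles: lipid head bead, lipid tail bead,
#' terminal (distal) tail bead, or water. Role names are fixed; GRO/XYZ output
#' encodes them as atom names H, T, TT and W.
#'
#' @return Character vector of the four role names.
#' @export
particle_roles <- function() c("head", "tail", "terminal_tail", "water")

#' Construct a particle configuration
#'
#' The universal container consumed by every collective variable, observable
#' and the toy dynamics engine: bead positions in nm, per-particle roles,
#' lipid membership, and an orthorhombic periodic box.
#'
#' @param positions Numeric matrix with one row per particle and columns
#'   x, y, z (nm).
#' @param roles Character vector of per-particle roles; see [particle_roles()].
#' @param lipid_ids Integer vector of lipid membership indices; `NA` for water.
#' @param box Numeric length-3 vector of box edge lengths (nm).
#' @param periodic Logical length-3 vector; which axes are periodic.
#'
#' @details Invariants enforced: finite coordinates, positive box edges, roles
#' drawn from [particle_roles()], and every lipid id owning exactly one head,
#' at least one tail and exactly one terminal tail bead.
#'
#' @return An object of class `particle_configuration`.
#' @export
particle_configuration <- function(positions, roles, lipid_ids, box,
                                   periodic = c(TRUE, TRUE, TRUE)) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L)
    stop("`positions` must have 3 columns (x, y, z in nm)")
  n <- nrow(positions)
  roles <- as.character(roles)
  lipid_ids <- as.integer(lipid_ids)
  box <- as.numeric(box)
  periodic <- as.logical(periodic)
  if (length(roles) != n || length(lipid_ids) != n)
    stop("`roles` and `lipid_ids` must have one entry per particle")
  if (length(box) != 3L || length(periodic) != 3L)
    stop("`box` and `periodic` must have length 3")
  obj <- structure(
    list(positions = positions, roles = roles, lipid_ids = lipid_ids,
         box = box, periodic = periodic),
    class = "particle_configuration")
  validate_configuration(obj)
  obj
}

#' Validate a particle configuration
#'
#' @param config A `particle_configuration`.
#' @return Invisibly, `config` (errors on violation).
#' @export
validate_configuration <- function(config) {
  stopifnot(inherits(config, "particle_configuration"))
  if (!all(is.finite(config$positions)))
    stop("all coordinates must be finite")
  if (!all(is.finite(config$box)) || any(config$box <= 0))
    stop("box edges must be positive and finite")
  bad <- setdiff(unique(config$roles), particle_roles())
  if (length(bad))
    stop("unknown roles: ", paste(bad, collapse = ", "))
  is_water <- config$roles == "water"
  if (any(is.na(config$lipid_ids) & !is_water))
    stop("non-water particles must carry a lipid id")
  if (any(!is.na(config$lipid_ids) & is_water))
    stop("water particles must not carry a lipid id")
  ids <- config$lipid_ids[!is_water]
  if (length(ids)) {
    for (role in c("head", "terminal_tail")) {
      cnt <- table(config$lipid_ids[config$roles == role])
      if (length(cnt) != length(unique(ids)) || any(cnt != 1L))
        stop("every lipid must own exactly one ", role, " bead")
    }
    cnt_t <- table(config$lipid_ids[config$roles == "tail"])
    if (length(cnt_t) != length(unique(ids)) || any(cnt_t < 1L))
      stop("every lipid must own at least one tail bead")
  }
  invisible(config)
}

#' @export
print.particle_configuration <- function(x, ...) {
  cnt <- table(factor(x$roles, levels = particle_roles()))
  cat("<particle_configuration>\n")
  cat(sprintf("  particles: %d (%d lipids, %d water)\n",
              nrow(x$positions),
              length(unique(x$lipid_ids[!is.na(x$lipid_ids)])),
              cnt[["water"]]))
  cat(sprintf("  roles: H=%d T=%d TT=%d W=%d\n", cnt[["head"]], cnt[["tail"]],
              cnt[["terminal_tail"]], cnt[["water"]]))
  cat(sprintf("  box: %.3f x %.3f x %.3f nm (periodic: %s)\n",
              x$box[1], x$box[2], x$box[3],
              paste(ifelse(x$periodic, "+", "-"), collapse = "")))
  invisible(x)
}

#' Number of particles in a configuration
#' @param config A `particle_configuration`.
#' @return Integer count.
#' @export
n_particles <- function(config) nrow(config$positions)

#' Role counts of a configuration
#' @param config A `particle_configuration`.
#' @return Named integer vector over [particle_roles()].
#' @export
role_counts <- function(config) {
  out <- table(factor(config$roles, levels = particle_roles()))
  setNames(as.integer(out), names(out))
}

#' Wrap all particles into the primary box
#'
#' Periodic axes are wrapped into `[0, L)`; non-periodic axes are left alone.
#'
#' @param config A `particle_configuration`.
#' @return The wrapped configuration.
#' @export
wrap_configuration <- function(config) {
  for (k in 1:3) {
    if (config$periodic[k]) {
      L <- config$box[k]
      config$positions[, k] <- config$positions[, k] - L * floor(config$positions[, k] / L)
    }
  }
  config
}

#' Center of geometry of the lipid beads
#'
#' @param config A `particle_configuration`.
#' @return Numeric length-3 vector (nm). Computed as the plain mean of all
#'   lipid bead positions (builders produce membranes that do not straddle a
#'   periodic boundary, so no minimum-image unwrapping is applied).
#' @export
lipid_center <- function(config) {
  keep <- config$roles != "water"
  if (!any(keep)) stop("configuration contains no lipid beads")
  colMeans(config$positions[keep, , drop = FALSE])
}

# integer role codes shared with the C++ kernels: 0=head 1=tail 2=terminal 3=water
role_codes <- function(roles) {
  match(roles, particle_roles()) - 1L
}
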