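#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point SASA: each atom is expanded by the probe radius,
#' `n_points` quasi-uniform points (golden-spiral lattice) are placed on the
#' expanded sphere, and a point is exposed when it lies outside every other
#' atom's expanded sphere. The atom's area is 4 pi (r + w)^2 times its
#' exposed fraction. Periodic images are not considered: the solute is
#' assumed compact relative to the box.
#'
#' @param coords `n_atoms x 3` matrix (nm).
#' @param radii Per-atom radii (nm); scalar recycled.
#' @param probe Probe radius (nm), default 0.14 (water).
#' @param n_points Sphere points per atom, >= 32.
#' @return Numeric vector of per-atom areas (nm^2).
#' @export
sasa_atoms <- function(coords, radii = 0.15, probe = 0.14, n_points = 960L) {
  n_points <- as.integer(n_points)
  if (n_points < 32L) stop("n_points < 32: below the accuracy floor")
  nat <- nrow(coords)
  radii <- rep_len(radii, nat)
  sp <- sphere_points(n_points)
  rex <- radii + probe
  out <- numeric(nat)
  # neighbour prefilter
  for (i in seq_len(nat)) {
    d <- sweep(coords, 2, coords[i, ])
    dist2 <- rowSums(d * d)
    nb <- which(dist2 < (rex[i] + rex)^2 & seq_len(nat) != i)
    if (!length(nb)) { out[i] <- 4 * pi * rex[i]^2; next }
    pts <- sweep(sp * rex[i], 2, coords[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- sweep(pts[exposed, , drop = FALSE], 2, coords[j, ])
      exposed[exposed] <- rowSums(dj * dj) >= rex[j]^2
    }
    out[i] <- 4 * pi * rex[i]^2 * mean(exposed)
  }
  out
}

# Deterministic quasi-uniform unit-sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-monomer SASA in the context of the full solute
#'
#' @param coords Frame coordinates (`n_atoms x 3`, nm).
#' @param topo A [stack_topology()].
#' @param radii Per-atom radii (nm); scalar recycled.
#' @param probe Probe radius (nm).
#' @param n_points Sphere points per atom.
#' @return Named numeric vector, nm^2 per monomer (sum over its atoms).
#' @export
sasa_per_monomer <- function(coords, topo, radii = 0.15, probe = 0.14,
                             n_points = 960L) {
  a <- sasa_atoms(coords, radii, probe, n_points)
  vapply(topo$monomers, function(m) sum(a[m$atoms]), numeric(1))
}

#' Time-averaged per-monomer SASA over a trajectory
#'
#' @param traj A [stack_trajectory()].
#' @param topo A [stack_topology()].
#' @param stride Evaluate every `stride`-th frame.
#' @inheritParams sasa_per_monomer
#' @return Named numeric vector of per-monomer time averages (nm^2).
#' @export
sasa_series_mean <- function(traj, topo, radii = 0.15, probe = 0.14,
                             n_points = 192L, stride = 1L) {
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  acc <- numeric(n_monomers(topo))
  for (f in frames) {
    acc <- acc + sasa_per_monomer(frame_coords(traj, f), topo, radii, probe, n_points)
  }
  setNames(acc / length(frames), monomer_ids(topo))
}

#' Aggregation propensity of a multi-stack assembly
#'
#' Ratio of the summed SASA of each stack taken alone (same internal
#' conformation) to the SASA of the whole assembly: AP = 1 when stacks do
#' not shield each other and grows as inter-stack burial increases.
#'
#' @param coords Frame coordinates (`n_atoms x 3`, nm).
#' @param topo A [stack_topology()] with at least 2 stacks.
#' @inheritParams sasa_per_monomer
#' @return A single number >= 1 (up to point-grid tolerance).
#' @export
aggregation_propensity <- function(coords, topo, radii = 0.15, probe = 0.14,
                                   n_points = 960L) {
  if (length(topo$stacks) < 2) stop("aggregation propensity undefined for a single stack")
  nat <- nrow(coords)
  radii <- rep_len(radii, nat)
  total <- sum(sasa_atoms(coords, radii, probe, n_points))
  iso <- 0
  for (sid in names(topo$stacks)) {
    at <- sort(unlist(lapply(topo$monomers[topo$stacks[[sid]]], `[[`, "atoms")))
    iso <- iso + sum(sasa_atoms(coords[at, , drop = FALSE], radii[at], probe, n_points))
  }
  iso / total
}
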