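#' Per-monomer core centers
#'
#' Geometric center of each monomer's core subset at every frame; if the
#' monomer record carries a generator `center_atom`, that atom's position is
#' used directly (the synthetic motif's core-center point).
#'
#' @param traj A [stack_trajectory()].
#' @param topo A [stack_topology()].
#' @return `n_monomers x 3 x n_frames` array.
#' @export
core_centers <- function(traj, topo) {
  nm <- n_monomers(topo)
  nf <- n_frames(traj)
  out <- array(NA_real_, c(nm, 3, nf), dimnames = list(monomer_ids(topo), NULL, NULL))
  for (i in seq_len(nm)) {
    m <- topo$monomers[[i]]
    if (!is.null(m$center_atom)) {
      out[i, , ] <- traj$coords[m$center_atom, , ]
    } else {
      out[i, , ] <- apply(traj$coords[m$core, , , drop = FALSE], c(2, 3), mean)
    }
  }
  out
}

#' Per-monomer radial distribution function
#'
#' Histogram of all center-center minimum-image distances, averaged over
#' frames, corrected by the spherical shell volume 4 pi r^2 dr and divided
#' by the number of monomers. Deliberately *not* divided by a bulk density:
#' with this normalization the stacking peaks grow with polymer size
#' (higher neighbour statistics), which a density-normalized RDF would
#' suppress. Bins are half-open `[r, r + dr)`.
#'
#' @param traj A [stack_trajectory()].
#' @param topo A [stack_topology()].
#' @param r_max Histogram range (nm).
#' @param bin Bin width (nm), > 0 and < r_max.
#' @param centers Optional precomputed centers array (as [core_centers()]).
#' @return Data frame with columns `r` (bin centers), `g` (normalized
#'   curve) and `counts` (raw pair counts per bin, summed over frames).
#' @export
rdf_per_monomer <- function(traj, topo, r_max = 2, bin = 0.02, centers = NULL) {
  if (bin <= 0 || r_max <= bin) stop("require bin > 0 and r_max > bin")
  if (is.null(centers)) centers <- core_centers(traj, topo)
  nm <- dim(centers)[1]
  if (nm < 2) stop("need at least 2 centers")
  nf <- dim(centers)[3]
  breaks <- seq(0, r_max, by = bin)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  for (f in seq_len(nf)) {
    box <- if (traj$periodic) traj$box[f, ] else c(Inf, Inf, Inf)
    dm <- mic_dist(centers[, , f], box = box)
    d <- dm[upper.tri(dm)]
    d <- d[d < r_max]
    # half-open bins [r, r+dr): floor indexing
    idx <- pmin(nb, floor(d / bin) + 1L)
    counts <- counts + tabulate(idx, nbins = nb)
  }
  r_mid <- breaks[-1] - bin / 2
  shell <- 4 * pi * r_mid^2 * bin
  g <- (counts / nf) / shell / nm
  data.frame(r = r_mid, g = g, counts = counts)
}

#' Locate local maxima of an RDF curve
#'
#' @param rdf Data frame from [rdf_per_monomer()].
#' @param n Number of peaks to return (by increasing r).
#' @param min_g Ignore maxima below this height.
#' @return Numeric vector of peak positions (bin centers, nm).
#' @export
rdf_peaks <- function(rdf, n = 2L, min_g = 0) {
  g <- rdf$g
  k <- length(g)
  is_max <- c(FALSE, g[2:(k - 1)] > g[1:(k - 2)] & g[2:(k - 1)] >= g[3:k], FALSE)
  pos <- rdf$r[is_max & g > min_g]
  utils::head(pos, n)
}
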