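#' Dimer planarity angle series
#'
#' For each initial dimer and frame, fits a plane to each partner's core
#' atoms (the plane normal is the smallest principal axis of the centered
#' coordinates) and reports the angle between the two planes, folded to
#' `[0, 90]` degrees. The planar fraction is the fraction of dimer-frames
#' with angle below `threshold`.
#'
#' @param traj A [stack_trajectory()].
#' @param topo A [stack_topology()]; every monomer's core subset must
#'   contain at least 3 non-collinear atoms.
#' @param threshold Planarity threshold in degrees (default 20).
#' @return List with `angles` (dimers x frames matrix, degrees),
#'   `planar_fraction` (scalar), and `per_dimer_fraction`.
#' @export
dimer_planarity <- function(traj, topo, threshold = 20) {
  nf <- n_frames(traj)
  nd <- length(topo$dimers0)
  ang <- matrix(NA_real_, nd, nf,
                dimnames = list(vapply(topo$dimers0, paste, character(1),
                                       collapse = "-"), NULL))
  normal_of <- function(xyz) {
    cc <- sweep(xyz, 2, colMeans(xyz))
    sv <- svd(cc)
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
      stop("collinear core atoms: plane undefined")
    }
    sv$v[, 3]
  }
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    for (k in seq_len(nd)) {
      d <- topo$dimers0[[k]]
      n1 <- normal_of(co[topo$monomers[[d[1]]]$core, , drop = FALSE])
      n2 <- normal_of(co[topo$monomers[[d[2]]]$core, , drop = FALSE])
      cang <- min(1, abs(sum(n1 * n2)))
      ang[k, f] <- acos(cang) * 180 / pi
    }
  }
  list(angles = ang,
       planar_fraction = mean(ang < threshold),
       per_dimer_fraction = rowMeans(ang < threshold),
       threshold = threshold)
}
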