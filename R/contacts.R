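#' Inter-stack atomic contacts per monomer
#'
#' For every monomer and frame, counts atom pairs (one atom in the monomer,
#' one in any *other* stack, both within the chosen scope) whose
#' minimum-image distance is below `cutoff`. Reported per monomer per frame
#' together with tip/backbone class averages.
#'
#' @param traj A [stack_trajectory()].
#' @param topo A [stack_topology()] with >= 2 stacks.
#' @param cutoff Contact distance (nm), > 0.
#' @param scope `"all"` (all solute atoms) or `"core"` (core subsets only,
#'   i.e. excluding side-chain contacts).
#' @param tip_depth Tip depth passed to [label_tips()] (default 2: end
#'   dimers and their first neighbours).
#' @return List with `nc` (monomers x frames matrix), `tip_mean` and
#'   `backbone_mean` (per-frame class averages) and `labels`.
#' @export
inter_stack_contacts <- function(traj, topo, cutoff = 0.5,
                                 scope = c("all", "core"), tip_depth = 2L) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  scope <- match.arg(scope)
  if (length(topo$stacks) < 2) stop("need at least 2 stacks")
  nm <- n_monomers(topo)
  ids <- monomer_ids(topo)
  atom_sets <- lapply(topo$monomers, function(m)
    if (scope == "core") m$core else m$atoms)
  atom_all <- unlist(atom_sets)
  atom_owner <- rep(seq_len(nm), lengths(atom_sets))
  atom_stack <- vapply(topo$monomers, function(m) m$stack, character(1))[atom_owner]
  nf <- n_frames(traj)
  nc <- matrix(0L, nm, nf, dimnames = list(ids, NULL))
  for (f in seq_len(nf)) {
    box <- if (traj$periodic) traj$box[f, ] else c(Inf, Inf, Inf)
    X <- traj$coords[atom_all, , f]
    dm <- mic_dist(X, box = box)
    hit <- dm < cutoff
    diag(hit) <- FALSE
    other <- outer(atom_stack, atom_stack, `!=`)
    hit <- hit & other
    cnt <- rowSums(hit)
    nc[, f] <- as.integer(rowsum(cnt, atom_owner))
  }
  labels <- label_tips(topo, tip_depth)
  tip_mean <- colMeans(nc[labels == "tip", , drop = FALSE])
  backbone_mean <- if (any(labels == "backbone")) {
    colMeans(nc[labels == "backbone", , drop = FALSE])
  } else rep(NA_real_, nf)
  list(nc = nc, tip_mean = tip_mean, backbone_mean = backbone_mean,
       labels = labels, cutoff = cutoff, scope = scope)
}
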