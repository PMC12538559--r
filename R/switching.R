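#' Rational switching-function parameters for H-bond coordination
#'
#' The PLUMED-style rational switching function used to count dimerization
#' hydrogen bonds: for a donor-acceptor distance r the weight is 1 for
#' r <= D0, and otherwise s = (1 - x^n)/(1 - x^m) with x = (r - D0)/R0.
#' Defaults R0 = 0.12 nm, D0 = 0.27 nm with exponents n = 6, m = 12.
#'
#' @param R0 Switching width in nm.
#' @param D0 Distance offset in nm.
#' @param n_exp,m_exp Rational exponents, `m_exp > n_exp > 0`.
#' @return A list of class `switching_params`.
#' @export
switching_params <- function(R0 = 0.12, D0 = 0.27, n_exp = 6L, m_exp = 12L) {
  stopifnot(R0 > 0, D0 >= 0, n_exp > 0, m_exp > n_exp)
  structure(list(R0 = R0, D0 = D0, n_exp = as.integer(n_exp),
                 m_exp = as.integer(m_exp)), class = "switching_params")
}

#' Continuous hydrogen-bond weight of a donor-acceptor distance
#'
#' @param r Distance(s) in nm, `r >= 0`. Vectorized.
#' @param params A [switching_params()].
#' @return Weight(s) in `[0, 1]`, continuous and non-increasing in r. The
#'   removable singularity at x = 1 (r = D0 + R0) evaluates to n/m.
#' @examples
#' switching_value(0.27)            # 1
#' switching_value(0.39)            # 6/12 = 0.5
#' switching_value(0.51)            # 63/4095
#' @export
switching_value <- function(r, params = switching_params()) {
  stopifnot(all(r >= 0))
  x <- (r - params$D0) / params$R0
  s <- numeric(length(r))
  s[x <= 0] <- 1
  pos <- which(x > 0)
  if (length(pos)) {
    xp <- x[pos]
    n <- params$n_exp; m <- params$m_exp
    near1 <- abs(xp - 1) < 1e-8
    out <- numeric(length(xp))
    out[near1] <- n / m
    reg <- !near1
    out[reg] <- (1 - xp[reg]^n) / (1 - xp[reg]^m)
    s[pos] <- out
  }
  s
}

#' Continuous dimerization H-bond count per dimer
#'
#' Each dimer contributes four donor-acceptor atom pairs; the count is the
#' sum of switching weights of the four minimum-image pair distances, a
#' continuous number in `[0, 4]`.
#'
#' @param coords Frame coordinates (`n_atoms x 3`, nm).
#' @param pairing List of dimers; each element is a `4 x 2` integer matrix of
#'   (atom in monomer a, atom in monomer b) rows.
#' @param params A [switching_params()].
#' @param box Length-3 box for minimum-image distances.
#' @return Numeric vector, one count per dimer.
#' @export
count_hb_dim <- function(coords, pairing, params = switching_params(),
                         box = c(Inf, Inf, Inf)) {
  vapply(pairing, function(pp) {
    if (max(pp) > nrow(coords)) stop("pairing references atom beyond frame")
    d <- mic_pair_dist(coords[pp[, 1], , drop = FALSE],
                       coords[pp[, 2], , drop = FALSE], box)
    sum(switching_value(d, params))
  }, numeric(1))
}

# The four (a, b) hb atom pairs of each initial dimer: atom k of the first
# partner's quadruple is matched with atom k of the second's.
dimer0_pairing <- function(topo) {
  lapply(topo$dimers0, function(d) {
    cbind(topo$monomers[[d[1]]]$hb, topo$monomers[[d[2]]]$hb)
  })
}

#' Initial-dimer H-bond count time series
#'
#' Evaluates, at every frame, how many of the four t = 0 dimerization
#' hydrogen bonds each dimer retains -- always against the t = 0 partner
#' pairing, regardless of later re-pairing. A dimer that ruptures and whose
#' monomers later bind *different* partners therefore stays low: by design
#' this series cannot detect dimerization of monomers that were not coupled
#' in the starting polymer.
#'
#' @param traj A [stack_trajectory()].
#' @param topo A [stack_topology()].
#' @param params A [switching_params()].
#' @return An object of class `hb_series`: list with `dimer` (dimers x
#'   frames matrix of counts), `monomer` (monomers x frames matrix; each
#'   monomer inherits its initial dimer's series), `times`.
#' @export
hb_dim0_series <- function(traj, topo, params = switching_params()) {
  pairing <- dimer0_pairing(topo)
  nf <- n_frames(traj)
  box_of <- function(i) if (traj$periodic) traj$box[i, ] else c(Inf, Inf, Inf)
  dm <- vapply(seq_len(nf), function(i) {
    count_hb_dim(frame_coords(traj, i), pairing, params, box_of(i))
  }, numeric(length(pairing)))
  dm <- matrix(dm, nrow = length(pairing))
  rownames(dm) <- vapply(topo$dimers0, paste, character(1), collapse = "-")
  mono <- matrix(NA_real_, n_monomers(topo), nf,
                 dimnames = list(monomer_ids(topo), NULL))
  for (k in seq_along(topo$dimers0)) {
    mono[topo$dimers0[[k]], ] <- rep(dm[k, ], each = 2)
  }
  structure(list(dimer = dm, monomer = mono, times = traj$times,
                 params = params), class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat("hb_series:", nrow(x$dimer), "dimers x", ncol(x$dimer), "frames;",
      "frame-0 mean =", signif(mean(x$dimer[, 1]), 4), "\n")
  invisible(x)
}
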