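#' Interaction centers for the dynamic descriptors
#'
#' Per-monomer center of mass of the 4-atom hydrogen-bond quadruple, per
#' frame -- the arrangement of these centers is informative about both
#' dimerization and stacking.
#'
#' @param traj A [stack_trajectory()].
#' @param topo A [stack_topology()].
#' @return `n_monomers x 3 x n_frames` array.
#' @export
soap_centers <- function(traj, topo) {
  nm <- n_monomers(topo)
  nf <- n_frames(traj)
  out <- array(NA_real_, c(nm, 3, nf),
               dimnames = list(monomer_ids(topo), NULL, NULL))
  for (i in seq_len(nm)) {
    out[i, , ] <- apply(traj$coords[topo$monomers[[i]]$hb, , , drop = FALSE],
                        c(2, 3), mean)
  }
  out
}

#' tauSOAP time series: frame-to-frame SOAP variation per center
#'
#' For every center the raw signal is the Euclidean distance between its
#' unit-norm SOAP vectors at consecutive frames; the tauSOAP series is the
#' min-max normalization of the raw values to `[0, 1]`, by default over the
#' whole dataset (all centers and frames), so 0 marks the most static and 1
#' the most dynamic neighbourhood observed. A degenerate range (static
#' trajectory) normalizes to all zeros. Values are defined from the second
#' frame onward.
#'
#' @param traj A [stack_trajectory()] with >= 2 frames.
#' @param topo A [stack_topology()].
#' @param spec A [soap_spec()].
#' @param normalize `"dataset"` (min-max over everything) or `"per-center"`.
#' @param stride Frame stride defining the time interval Delta-t.
#' @param smooth_window Odd window length of a centered moving average
#'   applied to the raw series per center before normalization (1 = raw,
#'   the default). A window of ~5 frames is recommended before mixture
#'   clustering and event detection: sustained dynamic episodes keep their
#'   level while single-frame flickers and noise tails are suppressed.
#' @return Object of class `tausoap_series`: `raw` and `tau` (centers x
#'   intervals matrices), `times` (right endpoints), `dt`, `empty` (logical
#'   matrix marking isolated centers at the interval's right endpoint).
#' @export
tau_soap_series <- function(traj, topo, spec = soap_spec(),
                            normalize = c("dataset", "per-center"),
                            stride = 1L, smooth_window = 1L) {
  normalize <- match.arg(normalize)
  smooth_window <- as.integer(smooth_window)
  stopifnot(smooth_window >= 1L, smooth_window %% 2L == 1L)
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  if (length(frames) < 2L) stop("tauSOAP needs at least 2 frames")
  centers <- soap_centers(traj, topo)
  nm <- dim(centers)[1]
  vecs_prev <- NULL
  raw <- matrix(NA_real_, nm, length(frames) - 1L,
                dimnames = list(monomer_ids(topo), NULL))
  empty <- matrix(FALSE, nm, length(frames) - 1L)
  for (k in seq_along(frames)) {
    f <- frames[k]
    box <- if (traj$periodic) traj$box[f, ] else c(Inf, Inf, Inf)
    vecs <- soap_vector(centers[, , f], spec, box)
    if (k > 1L) {
      raw[, k - 1L] <- sqrt(rowSums((vecs - vecs_prev)^2))
      empty[, k - 1L] <- attr(vecs, "empty")
    }
    vecs_prev <- vecs
  }
  sm <- if (smooth_window > 1L) {
    t(apply(raw, 1, moving_average, w = smooth_window))
  } else raw
  tau <- normalize_minmax(sm, per_center = normalize == "per-center")
  structure(list(raw = raw, tau = tau, times = traj$times[frames[-1]],
                 dt = traj$dt_frame * as.integer(stride), empty = empty,
                 spec = spec, normalize = normalize,
                 smooth_window = smooth_window),
            class = "tausoap_series")
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

normalize_minmax <- function(raw, per_center = FALSE) {
  scale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) <= 0) return(x * 0)
    (x - rng[1]) / diff(rng)
  }
  if (per_center) t(apply(raw, 1, scale01)) else
    matrix(scale01(raw), nrow = nrow(raw), dimnames = dimnames(raw))
}

#' @export
print.tausoap_series <- function(x, ...) {
  cat("tausoap_series:", nrow(x$tau), "centers x", ncol(x$tau),
      "intervals, dt =", x$dt, "ps; mean tau =", signif(mean(x$tau), 4), "\n")
  invisible(x)
}

#' LENS neighbour-shuffling series
#'
#' LENS_i(t) = |N_i(t) xor N_i(t-1)| / (|N_i(t)| + |N_i(t-1)|), the
#' symmetric difference of the center's neighbour-id sets between
#' consecutive frames over the sum of their sizes: 0 for a static
#' neighbour list, 1 for complete replacement, and 0 by convention when
#' both sets are empty.
#'
#' @param traj A [stack_trajectory()] with >= 2 frames.
#' @param topo A [stack_topology()].
#' @param cutoff Neighbour cutoff (nm), > 0.
#' @return Matrix centers x (frames - 1) of values in `[0, 1]`.
#' @export
lens_series <- function(traj, topo, cutoff = 0.75) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  nf <- n_frames(traj)
  if (nf < 2L) stop("LENS needs at least 2 frames")
  centers <- soap_centers(traj, topo)
  nm <- dim(centers)[1]
  nb_of <- function(f) {
    box <- if (traj$periodic) traj$box[f, ] else c(Inf, Inf, Inf)
    dm <- mic_dist(centers[, , f], box = box)
    lapply(seq_len(nm), function(i) which(dm[i, ] < cutoff & seq_len(nm) != i))
  }
  out <- matrix(NA_real_, nm, nf - 1L, dimnames = list(monomer_ids(topo), NULL))
  prev <- nb_of(1L)
  for (f in 2:nf) {
    cur <- nb_of(f)
    for (i in seq_len(nm)) {
      a <- prev[[i]]; b <- cur[[i]]
      tot <- length(a) + length(b)
      out[i, f - 1L] <- if (tot == 0L) 0 else
        (length(setdiff(a, b)) + length(setdiff(b, a))) / tot
    }
    prev <- cur
  }
  out
}
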