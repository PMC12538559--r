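#' SOAP descriptor specification
#'
#' Parameters of the smooth-overlap-of-atomic-positions power spectrum used
#' as the per-center structural fingerprint. Centers are one chemical
#' species (identical interacting moieties); each center's neighbour
#' density is a sum of Gaussians of width `sigma` at the other centers
#' within `r_cut`, expanded on `n_max` orthonormalized polynomial radial
#' functions times real spherical harmonics up to `l_max`.
#'
#' The object precomputes the radial overlap integrals
#' `I_nl(R) = int g_n(r) r^2 exp(-a (r-R)^2) ibar_l(2 a r R) dr`
#' (with `a = 1/(2 sigma^2)` and `ibar_l` the exponentially scaled modified
#' spherical Bessel function) on a fine distance grid, so per-neighbour
#' evaluation is a table lookup.
#'
#' @param r_cut Neighbourhood cutoff (nm).
#' @param n_max Number of radial basis functions.
#' @param l_max Angular band limit.
#' @param sigma Gaussian smearing width (nm).
#' @param cutoff_width Width (nm) of the smooth radial cutoff ramp: a
#'   neighbour at distance R enters the density with weight 1 for
#'   `R <= r_cut - cutoff_width`, decaying as cos^2 to 0 at `r_cut`, so the
#'   descriptor is continuous as neighbours cross the cutoff. 0 disables
#'   the ramp (hard cutoff).
#' @param n_quad Gauss-Legendre nodes per radial integral.
#' @param n_grid Size of the `I_nl` interpolation grid.
#' @return An object of class `soap_spec`.
#' @export
soap_spec <- function(r_cut = 0.6, n_max = 8L, l_max = 6L, sigma = 0.05,
                      cutoff_width = 0.15, n_quad = 48L, n_grid = 1200L) {
  stopifnot(r_cut > 0, n_max >= 1, l_max >= 1, sigma > 0,
            cutoff_width >= 0, cutoff_width < r_cut)
  n_max <- as.integer(n_max); l_max <- as.integer(l_max)
  # orthonormalize phi_k(r) = ((rc - r)/rc)^(k+2), k = 1..n_max, wrt r^2 dr
  S <- matrix(0, n_max, n_max)
  for (i in 1:n_max) for (j in 1:n_max) {
    a <- i + j + 4
    S[i, j] <- r_cut^3 * 2 / ((a + 1) * (a + 2) * (a + 3))
  }
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > max(es$values) * 1e-13
  W <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep)) %*%
    t(es$vectors[, keep, drop = FALSE])

  gl <- pracma::gaussLegendre(n_quad, -1, 1)
  spec <- structure(
    list(r_cut = r_cut, n_max = n_max, l_max = l_max, sigma = sigma,
         cutoff_width = cutoff_width, alpha = 1 / (2 * sigma^2), W = W,
         gl_x = gl$x, gl_w = gl$w),
    class = "soap_spec")
  grid <- seq(1e-6, r_cut, length.out = n_grid)
  tab <- vapply(grid, function(R) .soap_radial(R, spec),
                matrix(0, n_max, l_max + 1L))
  # flatten to (n_max*(l_max+1)) x n_grid for fast interpolation
  spec$grid <- grid
  spec$tab <- matrix(tab, nrow = n_max * (l_max + 1L))
  spec$dim <- (l_max + 1L) * n_max * (n_max + 1L) / 2L + 1L
  spec
}

# Exponentially scaled modified spherical Bessel i_l(x) e^{-x}.
.sph_bessel_i_scaled <- function(x, l) {
  out <- numeric(length(x))
  tiny <- x < 1e-8
  if (any(tiny)) {
    out[tiny] <- if (l == 0L) exp(-x[tiny]) else
      x[tiny]^l / prod(seq(1, 2 * l + 1, by = 2)) * exp(-x[tiny])
  }
  big <- !tiny
  if (any(big)) {
    xb <- x[big]
    out[big] <- sqrt(pi / (2 * xb)) * besselI(xb, l + 0.5, expon.scaled = TRUE)
  }
  out
}

# Radial overlap integrals I_nl(R): n_max x (l_max+1) matrix.
.soap_radial <- function(R, spec) {
  rc <- spec$r_cut; al <- spec$alpha
  w7 <- 7 * spec$sigma
  lo <- max(0, R - w7); hi <- min(rc, R + w7)
  r <- (hi - lo) / 2 * spec$gl_x + (hi + lo) / 2
  wq <- (hi - lo) / 2 * spec$gl_w
  phi <- outer(((rc - r) / rc), 1:spec$n_max + 2, `^`)   # nq x n_max
  gauss <- exp(-al * (r - R)^2) * r^2 * wq
  x <- 2 * al * r * R
  IB <- vapply(0:spec$l_max, function(l) .sph_bessel_i_scaled(x, l),
               numeric(length(r)))                        # nq x (l_max+1)
  raw <- t(phi * gauss) %*% IB                            # n_max x (l_max+1)
  spec$W %*% raw
}

# Smooth radial cutoff weight of a neighbour at distance R.
.cutoff_weight <- function(R, spec) {
  if (spec$cutoff_width <= 0) return(rep(1, length(R)))
  onset <- spec$r_cut - spec$cutoff_width
  w <- rep(1, length(R))
  ramp <- R > onset
  w[ramp] <- cos(pi / 2 * (R[ramp] - onset) / spec$cutoff_width)^2
  w[R >= spec$r_cut] <- 0
  w
}

# Interpolated I_nl for a vector of neighbour distances: returns
# (n_max*(l_max+1)) x k matrix.
.soap_radial_interp <- function(Rv, spec) {
  g <- spec$grid
  idx <- findInterval(Rv, g, all.inside = TRUE)
  w <- (Rv - g[idx]) / (g[idx + 1L] - g[idx])
  spec$tab[, idx, drop = FALSE] * rep(1 - w, each = nrow(spec$tab)) +
    spec$tab[, idx + 1L, drop = FALSE] * rep(w, each = nrow(spec$tab))
}

# Real spherical harmonics Y_lm for one l at directions given by cos(theta)
# and phi: returns (2l+1) x k matrix, rows m = -l..l.
.real_sph_harm <- function(l, ct, phi) {
  k <- length(ct)
  if (l == 0L) return(matrix(1 / sqrt(4 * pi), 1, k))
  P <- pracma::legendre(l, ct)                 # (l+1) x k, m = 0..l
  if (is.null(dim(P))) P <- matrix(P, ncol = k)
  out <- matrix(0, 2 * l + 1, k)
  for (m in 0:l) {
    N <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    if (m == 0L) {
      out[l + 1L, ] <- N * P[1, ]
    } else {
      out[l + 1L + m, ] <- sqrt(2) * N * P[m + 1L, ] * cos(m * phi)
      out[l + 1L - m, ] <- sqrt(2) * N * P[m + 1L, ] * sin(m * phi)
    }
  }
  out
}

#' SOAP power-spectrum vectors for a frame of centers
#'
#' Computes, for every center, the rotation-invariant power spectrum of the
#' Gaussian-smeared density of the *other* centers within `r_cut`,
#' L2-normalized. A center with an empty neighbourhood gets a fixed
#' reference vector (all-zero spectrum with a unit flag component), so its
#' consecutive-frame distance is zero while it stays isolated.
#'
#' @param centers `k x 3` matrix of center positions (nm).
#' @param spec A [soap_spec()].
#' @param box Length-3 box for minimum-image displacements.
#' @param subset Optional indices: compute vectors only for these centers
#'   (all centers still act as neighbours).
#' @return Matrix `length(subset) x dim` of unit-norm descriptor vectors;
#'   attribute `"empty"` flags isolated centers.
#' @export
soap_vector <- function(centers, spec = soap_spec(), box = c(Inf, Inf, Inf),
                        subset = NULL) {
  nmax <- spec$n_max; lmax <- spec$l_max
  nc <- nrow(centers)
  if (is.null(subset)) subset <- seq_len(nc)
  P <- matrix(0, length(subset), spec$dim)
  empty <- logical(length(subset))
  ut <- upper.tri(matrix(0, nmax, nmax), diag = TRUE)
  offdiag <- upper.tri(matrix(0, nmax, nmax), diag = FALSE)
  for (ii in seq_along(subset)) {
    i <- subset[ii]
    d <- mic_displacement(sweep(centers, 2, centers[i, ]), box)
    R <- sqrt(rowSums(d * d))
    nb <- which(R < spec$r_cut & seq_len(nc) != i & R > 1e-12)
    if (!length(nb)) {
      empty[ii] <- TRUE
      P[ii, spec$dim] <- 1
      next
    }
    Rv <- R[nb]
    ct <- d[nb, 3] / Rv
    ct <- pmin(1, pmax(-1, ct))
    phi <- atan2(d[nb, 2], d[nb, 1])
    Iall <- .soap_radial_interp(Rv, spec)       # (nmax*(lmax+1)) x k
    cw <- .cutoff_weight(Rv, spec)
    Iall <- Iall * rep(cw, each = nrow(Iall))
    vec <- numeric(spec$dim - 1L)
    pos <- 1L
    for (l in 0:lmax) {
      Y <- .real_sph_harm(l, ct, phi)           # (2l+1) x k
      Il <- Iall[(l * nmax + 1L):((l + 1L) * nmax), , drop = FALSE] # nmax x k
      C <- 4 * pi * (Il %*% t(Y))               # nmax x (2l+1)
      M <- C %*% t(C)                           # nmax x nmax
      M[offdiag] <- M[offdiag] * sqrt(2)
      block <- M[ut]
      vec[pos:(pos + length(block) - 1L)] <- block
      pos <- pos + length(block)
    }
    nrm <- sqrt(sum(vec^2))
    if (nrm > 0) vec <- vec / nrm
    P[ii, seq_along(vec)] <- vec
  }
  attr(P, "empty") <- empty
  P
}
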