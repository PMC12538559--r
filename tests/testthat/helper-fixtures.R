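# Shared fixtures: tiny topologies/trajectories built in code, plus the
# brute-force 3-D quadrature oracle for the SOAP power spectrum.

# A minimal hand-made topology: `n` monomers of 5 coincident-placeable atoms
# each (4 hb + 1 extra), one stack, paired consecutively.
tiny_topology <- function(n = 2L, stack = "S1") {
  monomers <- lapply(seq_len(n), function(i) {
    at <- (i - 1L) * 5L + 1:5
    list(id = paste0("M", i), stack = stack, atoms = at, hb = at[1:4],
         core = at)
  })
  dimers0 <- lapply(seq_len(n %/% 2L), function(k) {
    c(paste0("M", 2L * k - 1L), paste0("M", 2L * k))
  })
  stack_topology(monomers, dimers0,
                 axis_order = setNames(list(seq_len(n %/% 2L)), stack))
}

# Trajectory whose monomer hb-COM centers follow `centers`, an
# n_centers x 3 x n_frames array (all 5 atoms of a monomer coincide).
traj_from_centers <- function(centers, box = 100, dt = 1) {
  nm <- dim(centers)[1]; nf <- dim(centers)[3]
  coords <- array(NA_real_, c(nm * 5L, 3, nf))
  for (i in seq_len(nm)) for (a in 1:5) coords[(i - 1L) * 5L + a, , ] <- centers[i, , ]
  stack_trajectory(coords, (seq_len(nf) - 1) * dt, rep(box, 3))
}

# Independent SOAP oracle: direct 3-D numerical integration of the
# neighbour density against the radial basis and real spherical harmonics,
# with its own numerically orthonormalized basis. Returns the unit-norm
# power-spectrum vector (no empty-flag slot).
oracle_soap <- function(neighbors, r_cut = 0.6, n_max = 4L, l_max = 3L,
                        sigma = 0.05, cutoff_width = 0) {
  alpha <- 1 / (2 * sigma^2)
  glr <- pracma::gaussLegendre(90, 0, r_cut)
  glt <- pracma::gaussLegendre(48, 0, pi)
  np <- 96; phis <- (seq_len(np) - 0.5) * 2 * pi / np; wphi <- 2 * pi / np
  grid <- expand.grid(ir = seq_along(glr$x), it = seq_along(glt$x),
                      ip = seq_len(np))
  r <- glr$x[grid$ir]; th <- glt$x[grid$it]; ph <- phis[grid$ip]
  st <- sin(th)
  xyz <- cbind(r * st * cos(ph), r * st * sin(ph), r * cos(th))
  w <- glr$w[grid$ir] * glt$w[grid$it] * wphi * r^2 * st
  Rj <- sqrt(rowSums(neighbors^2))
  cw <- if (cutoff_width > 0) {
    onset <- r_cut - cutoff_width
    ifelse(Rj <= onset, 1,
           ifelse(Rj >= r_cut, 0, cos(pi / 2 * (Rj - onset) / cutoff_width)^2))
  } else rep(1, length(Rj))
  rho <- rep(0, nrow(xyz))
  for (j in seq_len(nrow(neighbors))) {
    d <- sweep(xyz, 2, neighbors[j, ])
    rho <- rho + cw[j] * exp(-alpha * rowSums(d * d))
  }
  Phi <- outer((r_cut - glr$x) / r_cut, (1:n_max) + 2, `^`)
  S <- t(Phi) %*% (Phi * glr$w * glr$x^2)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  gvals <- outer((r_cut - r) / r_cut, (1:n_max) + 2, `^`) %*% t(W)
  Yfun <- function(l, m, th, ph) {
    P <- pracma::legendre(l, cos(th))
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - abs(m) + 1) - lgamma(l + abs(m) + 1)))
    if (m == 0) N * P[1, ]
    else if (m > 0) sqrt(2) * N * P[m + 1, ] * cos(m * ph)
    else sqrt(2) * N * P[-m + 1, ] * sin(-m * ph)
  }
  vec <- c()
  for (l in 0:l_max) {
    C <- matrix(0, n_max, 2 * l + 1)
    for (m in -l:l) {
      ylm <- Yfun(l, m, th, ph)
      for (n in 1:n_max) C[n, m + l + 1] <- sum(w * gvals[, n] * ylm * rho)
    }
    M <- C %*% t(C)
    off <- upper.tri(M)
    M[off] <- M[off] * sqrt(2)
    vec <- c(vec, M[upper.tri(M, diag = TRUE)])
  }
  vec / sqrt(sum(vec^2))
}

# Random 3-D rotation matrix (proper).
random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# The well-separated exchange scenario used for ground-truth recovery
# checks: tip ruptures only.
kmc_scenario <- function(seed, n_dimers = 20L, n_frames = 400L,
                         k_tip = 5e-4) {
  p <- synthetic_params(n_dimers = n_dimers, k_tip = k_tip, k_back = 0,
                        n_frames = n_frames, seed = seed)
  b <- build_stack(p)
  sim <- simulate_exchange(b$topology, b$coords0, p)
  list(params = p, topology = b$topology, coords0 = b$coords0,
       trajectory = sim$trajectory, truth = sim$truth)
}

truth_domain_labels <- function(truth) {
  map <- c(bound = "I", `stacked-unbound` = "II", travelling = "III")
  matrix(map[truth$states[, -1, drop = FALSE]], nrow = nrow(truth$states),
         dimnames = list(rownames(truth$states), NULL))
}

# Importance-sampling oracle for FES reweighting: samples drawn from the
# biased density exp(-(F* + V)/kT) with a known double well F* and static
# bias V = -0.9 F*; the reference per cell is the cell-integrated free
# energy -kT log int_cell exp(-F*/kT), the quantity the histogram-based
# estimator targets.
double_well_reweight_check <- function(n_samples = 1e5, n_bins = 33L) {
  kT <- kB * 298
  Fstar <- function(x) 12 * (x^2 - 1)^2
  fine <- seq(-1.6, 1.6, length.out = 4000L)
  step <- diff(fine[1:2])
  p_b <- exp(-(Fstar(fine) - 0.9 * Fstar(fine)) / kT)
  x <- sample(fine, n_samples, replace = TRUE, prob = p_b) +
    stats::runif(n_samples, -step / 2, step / 2)
  samples <- data.frame(cv = x, bias = -0.9 * Fstar(x))
  breaks <- seq(-1.65, 1.65, length.out = n_bins + 1L)
  fes <- reweight_fes(samples, kT, cv = "cv", breaks = list(breaks))
  Fref <- vapply(seq_len(n_bins), function(i) {
    xx <- seq(breaks[i], breaks[i + 1], length.out = 60L)
    -kT * log(sum(exp(-Fstar(xx) / kT)))
  }, numeric(1))
  Fref <- Fref - min(Fref)
  sampled <- !is.na(fes$F) & fes$counts > 50
  # both surfaces shifted to a common reference over the compared cells
  dF <- fes$F[sampled] - Fref[sampled]
  rmse <- sqrt(mean((dF - mean(dF))^2))
  list(rmse = rmse, fes = fes, samples = samples, kT = kT, breaks = breaks,
       Fref = Fref, sampled = sampled)
}
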