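spec_small <- soap_spec(n_max = 4L, l_max = 3L)

test_that("identical environments give identical SOAP vectors", {
  set.seed(1)
  nb <- matrix(rnorm(12, 0, 0.15), 4, 3)
  centers <- rbind(c(0, 0, 0), nb,
                   c(50, 50, 50), sweep(nb, 2, c(50, 50, 50), `+`))
  v <- soap_vector(centers, spec_small, subset = c(1L, 6L))
  expect_lt(1 - sum(v[1, ] * v[2, ]), 1e-10)
})

test_that("SOAP is invariant under rigid rotation of the environment", {
  set.seed(2)
  for (rep in 1:3) {
    nb <- matrix(rnorm(15, 0, 0.18), 5, 3)
    centers <- rbind(c(0, 0, 0), nb)
    vA <- soap_vector(centers, spec_small, subset = 1L)
    R <- random_rotation()
    vB <- soap_vector(centers %*% t(R), spec_small, subset = 1L)
    expect_lt(sqrt(sum((vA - vB)^2)), 1e-8)
  }
})

test_that("SOAP distances agree with a 3-D numerical-integration oracle", {
  cA <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.35, 0))
  cB <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 0.35, 0))
  spec0 <- soap_spec(n_max = 4L, l_max = 3L, cutoff_width = 0)
  vA <- soap_vector(cA, spec0, subset = 1L)
  vB <- soap_vector(cB, spec0, subset = 1L)
  dI <- 1 - sum(vA * vB)
  oA <- oracle_soap(cA[2:3, ])
  oB <- oracle_soap(cB[2:3, ])
  dO <- 1 - sum(oA * oB)
  expect_gt(dI, 0)
  expect_lt(abs(dI - dO), 1e-4)
  # the vectors themselves agree component-wise
  expect_lt(max(abs(vA[1, seq_along(oA)] - oA)), 1e-5)

  # and with the smooth cutoff ramp active
  vA2 <- soap_vector(cA, spec_small, subset = 1L)
  oA2 <- oracle_soap(cA[2:3, ], cutoff_width = 0.15)
  expect_lt(max(abs(vA2[1, seq_along(oA2)] - oA2)), 1e-5)
})

test_that("isolated centers get the flagged reference vector", {
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(10.3, 0, 0))
  v <- soap_vector(centers, spec_small)
  expect_true(attr(v, "empty")[1])
  expect_false(any(attr(v, "empty")[2:3]))
  expect_equal(v[1, ncol(v)], 1)
  expect_equal(sum(v[1, ]^2), 1)
})

test_that("tauSOAP is zero for a static trajectory and min-max normalized", {
  centers <- array(0, c(3, 3, 4))
  centers[2, 1, ] <- 0.4
  centers[3, 2, ] <- 0.45
  traj <- traj_from_centers(centers)
  topo <- tiny_topology(3L)
  ts <- tau_soap_series(traj, topo, spec_small)
  expect_true(all(ts$raw == 0))
  expect_true(all(ts$tau == 0))
  expect_error(tau_soap_series(traj_from_centers(centers[, , 1, drop = FALSE]),
                               topo, spec_small), "2 frames")
})

test_that("a center with a scrambled shell scores 1, static satellites 0", {
  # three satellites on a 0.5 nm shell around center 1, mutually > r_cut,
  # re-drawn each frame: satellite environments stay a single neighbour at
  # constant distance (rotation-invariant), center 1 sees angular churn
  set.seed(31)
  nf <- 8L
  centers <- array(NA_real_, c(4, 3, nf))
  for (f in seq_len(nf)) {
    repeat {
      dirs <- matrix(rnorm(9), 3, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      pts <- dirs * 0.5
      if (min(dist(pts)) > 0.62) break
    }
    centers[1, , f] <- 0
    centers[2:4, , f] <- pts
  }
  traj <- traj_from_centers(centers)
  topo <- tiny_topology(4L)
  ts <- tau_soap_series(traj, topo, spec_small)
  expect_true(all(ts$tau[2:4, ] < 1e-9))
  expect_true(all(ts$tau[1, ] > 0))
  expect_equal(max(ts$tau[1, ]), 1)
})

test_that("LENS measures neighbour-set replacement", {
  # static sets -> 0; full replacement -> 1; one of four swapped -> 0.25
  nf <- 3L
  centers <- array(NA_real_, c(6, 3, nf))
  ring <- function(ids_in) {
    # place selected neighbours within 0.7 of center 1, others far
    out <- matrix(0, 6, 3)
    out[1, ] <- 0
    ang <- seq(0, 2 * pi, length.out = 6)[-6]
    for (i in 2:6) {
      r <- if (i %in% ids_in) 0.5 else 5
      out[i, ] <- c(r * cos(ang[i - 1]), r * sin(ang[i - 1]), 0)
    }
    out
  }
  centers[, , 1] <- ring(c(2, 3, 4, 5))
  centers[, , 2] <- ring(c(2, 3, 4, 5))
  centers[, , 3] <- ring(c(2, 3, 4, 6))
  traj <- traj_from_centers(centers)
  topo <- tiny_topology(6L)
  lens <- lens_series(traj, topo, cutoff = 0.7)
  expect_equal(unname(lens[1, 1]), 0)
  expect_equal(unname(lens[1, 2]), 2 / 8)
  expect_true(all(lens >= 0 & lens <= 1))
  expect_error(lens_series(traj, topo, cutoff = 0), "cutoff")

  # complete replacement of equal-sized sets
  c2 <- array(NA_real_, c(5, 3, 2))
  c2[, , 1] <- ring(c(2, 3))[1:5, ]
  c2[, , 2] <- ring(c(4, 5))[1:5, ]
  l2 <- lens_series(traj_from_centers(c2), tiny_topology(5L), cutoff = 0.7)
  expect_equal(unname(l2[1, 1]), 1)
})

test_that("descriptors are invariant under a global rigid motion", {
  sc <- kmc_scenario(seed = 4L, n_dimers = 5L, n_frames = 20L, k_tip = 2e-3)
  traj <- sc$trajectory
  set.seed(77)
  R <- random_rotation(); shift <- c(1, -2, 0.5)
  traj2 <- traj
  traj2$periodic <- FALSE
  for (f in seq_len(dim(traj$coords)[3])) {
    traj2$coords[, , f] <- sweep(traj$coords[, , f] %*% t(R), 2, shift, `+`)
  }
  traj1 <- traj; traj1$periodic <- FALSE
  t1 <- tau_soap_series(traj1, sc$topology, spec_small)
  t2 <- tau_soap_series(traj2, sc$topology, spec_small)
  expect_equal(t2$raw, t1$raw, tolerance = 1e-7)
  l1 <- lens_series(traj1, sc$topology)
  l2 <- lens_series(traj2, sc$topology)
  expect_identical(l1, l2)
})

test_that("exchange dynamics orders tauSOAP by ground-truth state", {
  sc <- kmc_scenario(seed = 6L, n_dimers = 10L, n_frames = 150L, k_tip = 1e-3)
  ts <- tau_soap_series(sc$trajectory, sc$topology)
  truth <- sc$truth$states[, -1]
  expect_true(all(ts$tau >= 0 & ts$tau <= 1))
  m_bound <- mean(ts$tau[truth == "bound"])
  m_unb <- mean(ts$tau[truth == "stacked-unbound"])
  m_trav <- mean(ts$tau[truth == "travelling"])
  expect_gt(m_unb, m_bound)
  expect_gt(m_bound, m_trav)
  expect_lt(m_trav, 0.05)

  # LENS tells a coherent story: positive rank correlation on frames with
  # occupied neighbourhoods
  lens <- lens_series(sc$trajectory, sc$topology)
  keep <- !ts$empty
  rho <- suppressWarnings(
    stats::cor(ts$tau[keep], lens[keep], method = "spearman"))
  expect_gt(rho, 0)
})
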