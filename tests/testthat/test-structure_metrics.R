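test_that("switching function matches its closed forms and is monotone", {
  expect_identical(switching_value(0.27), 1)
  expect_identical(switching_value(0.1), 1)
  expect_equal(switching_value(0.39), 0.5, tolerance = 1e-9)
  expect_equal(switching_value(0.51), 63 / 4095, tolerance = 1e-12)
  # continuity across the removable singularity at x = 1
  eps <- 1e-9 * 0.12
  expect_lt(abs(switching_value(0.39 + eps) - 0.5), 1e-6)
  expect_lt(abs(switching_value(0.39 - eps) - 0.5), 1e-6)
  r <- seq(0, 2, length.out = 1e4)
  s <- switching_value(r)
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("hydrogen-bond counts sum switching weights over the quadruple", {
  place <- function(d) {
    # 4 pairs: first monomer's hb at origin-ish, partner's at distance d[k]
    co <- matrix(0, 10, 3)
    co[1:4, 2] <- (1:4) * 10           # separate the four pairs
    co[6:9, 2] <- (1:4) * 10
    co[6:9, 1] <- d
    co
  }
  pairing <- list(cbind(1:4, 6:9))
  expect_equal(count_hb_dim(place(rep(0.2, 4)), pairing), 4)
  expect_lt(count_hb_dim(place(rep(2.0, 4)), pairing), 0.001)
  expect_equal(count_hb_dim(place(c(0.2, 0.2, 0.39, 0.39)), pairing), 3,
               tolerance = 1e-9)
  expect_error(count_hb_dim(place(rep(0.2, 4))[1:8, ], pairing), "atom")

  # rigid motion invariance
  co <- place(c(0.25, 0.3, 0.35, 0.5))
  R <- with_seed_local <- local({set.seed(9); random_rotation()})
  co2 <- sweep(co %*% t(R), 2, c(1, -2, 3), `+`)
  expect_equal(count_hb_dim(co2, pairing), count_hb_dim(co, pairing),
               tolerance = 1e-12)
})

test_that("initial-dimer series tracks rupture and is blind to re-pairing", {
  # static generator trajectory: all series ~4
  p <- synthetic_params(n_dimers = 3L, k_tip = 0, k_back = 0, k_slide = 0,
                        k_rebind = 0, noise_sigma = 0.01, n_frames = 6L)
  b <- build_stack(p)
  suppressWarnings(sim <- simulate_exchange(b$topology, b$coords0, p))
  hb <- hb_dim0_series(sim$trajectory, b$topology)
  expect_true(all(abs(hb$dimer - 4) < 0.5))
  expect_true(all(abs(hb$dimer[, 1] - 4) < 0.5))

  # a planted tip rupture drops that dimer's series and it never recovers
  sc <- kmc_scenario(seed = 5L, n_dimers = 10L, n_frames = 150L, k_tip = 2e-3)
  rup <- sc$truth$events[sc$truth$events$type == "rupture", ]
  expect_gt(nrow(rup), 0L)
  hb2 <- hb_dim0_series(sc$trajectory, sc$topology)
  t_star <- rup$time[1]
  f_star <- findInterval(t_star, sc$trajectory$times) + 1L
  d_idx <- which(vapply(sc$topology$dimers0, function(d) rup$monomer[1] %in% d,
                        logical(1)))
  expect_lt(hb2$dimer[d_idx, min(f_star + 3L, ncol(hb2$dimer))], 1)
  # with no rebind to the same partner the series stays low
  reb <- sc$truth$events[sc$truth$events$type == "rebind", ]
  same_pair_rebind <- any(apply(reb, 1, function(e) {
    setequal(c(e[["monomer"]], e[["partner"]]),
             sc$topology$dimers0[[d_idx]])
  }))
  if (!same_pair_rebind) {
    expect_true(all(hb2$dimer[d_idx, (f_star + 3L):ncol(hb2$dimer)] < 1))
  }

  # blindness: a dimer re-formed from differently paired monomers reads ~4
  # under its new pairing while the t=0 series stays low
  co <- b$coords0
  m1 <- b$topology$monomers$M1; m4 <- b$topology$monomers$M4
  new_pairing <- list(cbind(m1$hb, m4$hb))
  co2 <- co
  co2[m4$atoms, ] <- co[b$topology$monomers$M2$atoms, ]  # M4 takes M2's slot
  co2[b$topology$monomers$M2$atoms, ] <- co[b$topology$monomers$M2$atoms, ] + 5
  expect_equal(count_hb_dim(co2, new_pairing), 4, tolerance = 1e-9)
  old_pairing <- stackdyn:::dimer0_pairing(b$topology)
  expect_lt(count_hb_dim(co2, old_pairing)[1], 0.01)
})

test_that("per-monomer RDF normalization and peak structure are correct", {
  # two fixed centers 0.5 nm apart: one nonzero bin
  centers <- array(0, c(2, 3, 3))
  centers[2, 1, ] <- 0.5
  traj <- traj_from_centers(centers)
  topo <- tiny_topology(2L)
  rdf <- rdf_per_monomer(traj, topo, r_max = 1, bin = 0.02)
  nz <- which(rdf$counts > 0)
  expect_length(nz, 1L)
  expect_true(abs(rdf$r[nz] - 0.5) <= 0.02)

  # ideal 20D lattice: first two maxima at the stacking and dimer spacings
  p <- synthetic_params(n_dimers = 20L, k_tip = 0, k_back = 0, k_slide = 0,
                        k_rebind = 0, noise_sigma = 0, n_frames = 2L)
  b <- build_stack(p)
  suppressWarnings(sim <- simulate_exchange(b$topology, b$coords0, p))
  rdf20 <- rdf_per_monomer(sim$trajectory, b$topology, r_max = 1.2, bin = 0.02)
  pk <- rdf_peaks(rdf20, 2, min_g = max(rdf20$g) * 0.05)
  expect_lt(abs(pk[1] - 0.37), 0.02 + 1e-9)
  expect_lt(abs(pk[2] - 0.6), 0.02 + 1e-9)

  # frame averaging: duplicating frames of a static trajectory changes nothing
  rdf1 <- rdf_per_monomer(traj_from_centers(centers[, , 1, drop = FALSE]),
                          topo, r_max = 1, bin = 0.02)
  expect_equal(rdf$g, rdf1$g, tolerance = 1e-12)

  # total pair count conserved before normalization
  set.seed(11)
  cr <- array(runif(8 * 3 * 2, 0, 0.9), c(8, 3, 2))
  trj <- traj_from_centers(cr, box = 100)
  tp8 <- tiny_topology(8L)
  rdf8 <- rdf_per_monomer(trj, tp8, r_max = 5, bin = 0.05)
  expect_equal(sum(rdf8$counts), 8 * 7 / 2 * 2)

  # relabelling invariance
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  rdf8p <- rdf_per_monomer(traj_from_centers(cr[perm, , , drop = FALSE]),
                           tp8, r_max = 5, bin = 0.05)
  expect_equal(rdf8p$g, rdf8$g, tolerance = 1e-12)

  expect_error(rdf_per_monomer(trj, tp8, r_max = 1, bin = 0), "bin")
  expect_error(rdf_per_monomer(trj, tp8, r_max = 0.01, bin = 0.05), "bin")
})

test_that("Shrake-Rupley SASA matches spheres, buries and rotates correctly", {
  one <- matrix(0, 1, 3)
  a <- sasa_atoms(one, radii = 0.15, probe = 0.14, n_points = 960L)
  expect_equal(a, 4 * pi * 0.29^2, tolerance = 0.02 * 4 * pi * 0.29^2)

  # far-apart atoms are additive
  two <- rbind(c(0, 0, 0), c(5, 0, 0))
  a2 <- sasa_atoms(two, radii = 0.15, probe = 0.14, n_points = 480L)
  expect_equal(a2, rep(4 * pi * 0.29^2, 2), tolerance = 1e-6)

  # an atom enclosed by a tight shell of neighbours is buried
  shell <- sphere_points_fixture <- stackdyn:::sphere_points(26) * 0.2
  a3 <- sasa_atoms(rbind(c(0, 0, 0), shell), radii = 0.15, probe = 0.14,
                   n_points = 480L)
  expect_lt(a3[1], 1e-6)

  # rotation invariance within grid tolerance; occlusion decreases area
  set.seed(21)
  cl <- matrix(rnorm(15, sd = 0.2), 5, 3)
  aA <- sasa_atoms(cl, radii = 0.15, n_points = 960L)
  R <- random_rotation()
  aB <- sasa_atoms(cl %*% t(R), radii = 0.15, n_points = 960L)
  expect_equal(sum(aB), sum(aA), tolerance = 0.01)
  aC <- sasa_atoms(rbind(cl, c(0.05, 0, 0)), radii = 0.15, n_points = 960L)
  expect_lt(sum(aC[1:5]), sum(aA))

  expect_error(sasa_atoms(one, n_points = 16L), "n_points")
})

test_that("aggregation propensity is 1 when stacks are apart and > 1 in contact", {
  p <- synthetic_params(n_dimers = 5L, n_frames = 1L, box = 30)
  far <- make_bundle(2L, p, spacing = 10)
  ap_far <- aggregation_propensity(far$coords0, far$topology, n_points = 480L)
  expect_equal(ap_far, 1, tolerance = 1e-6)

  near <- make_bundle(2L, p, spacing = 0.8)
  ap_near <- aggregation_propensity(near$coords0, near$topology, n_points = 480L)
  expect_gt(ap_near, 1)

  # AP is non-increasing as spacing grows on the rigid bundle
  aps <- vapply(c(0.8, 1.0, 1.5, 3, 10), function(sp) {
    bn <- make_bundle(2L, p, spacing = sp)
    aggregation_propensity(bn$coords0, bn$topology, n_points = 240L)
  }, numeric(1))
  expect_true(all(diff(aps) <= 1e-6))

  single <- build_stack(p)
  expect_error(aggregation_propensity(single$coords0, single$topology),
               "single stack")
})

test_that("inter-stack contacts count cutoff pairs and localize at tips", {
  p <- synthetic_params(n_dimers = 5L, n_frames = 1L, box = 30)
  far <- make_bundle(2L, p, spacing = 10)
  traj <- stack_trajectory(array(far$coords0, c(nrow(far$coords0), 3, 1)),
                           0, far$box)
  res <- inter_stack_contacts(traj, far$topology, cutoff = 0.5, tip_depth = 2L)
  expect_true(all(res$nc == 0))

  # two single-point "monomers" (core scope) 0.4 nm apart across stacks
  mono <- function(id, stack, off) {
    list(id = id, stack = stack, atoms = off + 1:5, hb = off + 1:4,
         core = off + 5L)
  }
  topo2 <- stack_topology(
    list(mono("M1", "S1", 0L), mono("M2", "S1", 5L),
         mono("M3", "S2", 10L), mono("M4", "S2", 15L)),
    dimers0 = list(c("M1", "M2"), c("M3", "M4")),
    axis_order = list(S1 = 1L, S2 = 2L))
  co <- matrix(0, 20, 3)
  co[1:9, 2] <- rep(c(5, 6), c(5, 4))     # hb atoms far from the cores
  co[11:19, 2] <- rep(c(-5, -6), c(5, 4))
  co[10, ] <- c(0, 0, 0)                  # core of M2
  co[20, ] <- c(0.4, 0, 0)                # core of M4
  co[5, ] <- c(0, 9, 0); co[15, ] <- c(0, -9, 0)
  tr2 <- stack_trajectory(array(co, c(20, 3, 1)), 0, c(50, 50, 50))
  res2 <- inter_stack_contacts(tr2, topo2, cutoff = 0.5, scope = "core",
                               tip_depth = 1L)
  expect_equal(unname(res2$nc["M2", 1]), 1L)
  expect_equal(unname(res2$nc["M4", 1]), 1L)
  expect_equal(unname(res2$nc["M1", 1]), 0L)

  # constructed bundle where only the end dimers interdigitate: move the
  # first dimer of stack 2 next to stack 1's first dimer; interior sites
  # stay out of reach
  p8 <- synthetic_params(n_dimers = 8L, n_frames = 1L, box = 30)
  near <- make_bundle(2L, p8, spacing = 3)
  co3 <- near$coords0
  s2_end <- unlist(lapply(near$topology$monomers[near$topology$stacks$S2[1:2]],
                          `[[`, "atoms"))
  co3[s2_end, 1] <- co3[s2_end, 1] - 2.7
  tr3 <- stack_trajectory(array(co3, c(nrow(co3), 3, 1)), 0, near$box)
  res3 <- inter_stack_contacts(tr3, near$topology, cutoff = 0.5, tip_depth = 2L)
  expect_gt(mean(res3$tip_mean), 0)
  expect_equal(mean(res3$backbone_mean), 0)
  expect_error(inter_stack_contacts(tr3, near$topology, cutoff = -1), "cutoff")
})

test_that("dimer planarity measures the inter-plane angle", {
  p <- synthetic_params(n_dimers = 1L, n_frames = 1L, noise_sigma = 0)
  b <- build_stack(p)
  traj <- stack_trajectory(array(b$coords0, c(10, 3, 1)), 0, b$box)
  pl <- dimer_planarity(traj, b$topology)
  expect_equal(unname(pl$angles[1, 1]), 0, tolerance = 1e-6)
  expect_equal(pl$planar_fraction, 1)

  rot_about_y <- function(th) {
    matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  }
  tilt <- function(deg) {
    co <- b$coords0
    at <- b$topology$monomers$M2$atoms
    ctr <- colMeans(co[at, ])
    co[at, ] <- sweep(sweep(co[at, ], 2, ctr) %*% t(rot_about_y(deg * pi / 180)),
                      2, ctr, `+`)
    stack_trajectory(array(co, c(10, 3, 1)), 0, b$box)
  }
  expect_equal(unname(dimer_planarity(tilt(90), b$topology)$angles[1, 1]), 90,
               tolerance = 1e-6)
  expect_equal(unname(dimer_planarity(tilt(30), b$topology)$angles[1, 1]), 30,
               tolerance = 1e-6)

  # collinear core atoms are rejected
  co <- b$coords0
  co[b$topology$monomers$M1$atoms, ] <- cbind(1:5, 1:5, 1:5)
  trc <- stack_trajectory(array(co, c(10, 3, 1)), 0, b$box)
  expect_error(dimer_planarity(trc, b$topology), "collinear")
})

test_that("ruptured monomers are more solvent-exposed and less bonded", {
  sc <- kmc_scenario(seed = 8L, n_dimers = 10L, n_frames = 120L, k_tip = 2e-3)
  hb <- hb_dim0_series(sc$trajectory, sc$topology)
  sasa <- sasa_series_mean(sc$trajectory, sc$topology, stride = 12L,
                           n_points = 96L)
  ct <- suppressWarnings(
    stats::cor.test(rowMeans(hb$monomer), sasa, method = "spearman",
                    exact = FALSE))
  expect_lt(unname(ct$estimate), 0)
})
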