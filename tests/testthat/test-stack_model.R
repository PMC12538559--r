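test_that("generator topology round-trips through JSON + XYZ", {
  p <- synthetic_params(n_dimers = 2L, n_frames = 1L, noise_sigma = 0)
  b <- build_stack(p)
  dir <- withr::local_tempdir()
  write_topology_json(b$topology, file.path(dir, "topo.json"))
  traj <- stack_trajectory(array(b$coords0, c(nrow(b$coords0), 3, 1)),
                           0, b$box)
  write_trajectory_xyz(traj, file.path(dir, "frame0.xyz"))
  topo <- load_topology(file.path(dir, "frame0.xyz"), file.path(dir, "topo.json"))
  expect_length(topo$monomers, 4L)
  expect_length(topo$dimers0, 2L)
  expect_equal(topo$axis_order$S1, b$topology$axis_order$S1)
  expect_equal(topo$monomers$M1$hb, b$topology$monomers$M1$hb)

  p20 <- synthetic_params(n_dimers = 20L, n_frames = 1L)
  b20 <- build_stack(p20)
  expect_length(b20$topology$monomers, 40L)
  expect_length(b20$topology$dimers0, 20L)
  expect_length(b20$topology$axis_order$S1, 20L)
})

test_that("topology validation names the offending monomer", {
  p <- synthetic_params(n_dimers = 2L, n_frames = 1L)
  b <- build_stack(p)
  dir <- withr::local_tempdir()
  traj <- stack_trajectory(array(b$coords0, c(nrow(b$coords0), 3, 1)), 0, b$box)
  write_trajectory_xyz(traj, file.path(dir, "frame0.xyz"))
  ann <- jsonlite::read_json(write_topology_json(b$topology, file.path(dir, "t.json")))
  ann$monomers[[2]]$hb <- ann$monomers[[2]]$hb[1:3]   # drop one quadruple atom
  expect_error(load_topology(file.path(dir, "frame0.xyz"), ann), "M2")
  ann2 <- jsonlite::read_json(file.path(dir, "t.json"))
  ann2$dimers0[[1]][[2]] <- "M99"
  expect_error(load_topology(file.path(dir, "frame0.xyz"), ann2), "M99")
  ann3 <- jsonlite::read_json(file.path(dir, "t.json"))
  ann3$monomers[[1]]$hb <- NULL
  expect_error(load_topology(file.path(dir, "frame0.xyz"), ann3), "M1")
})

test_that("axis order is inferred from frame-0 geometry when absent", {
  p <- synthetic_params(n_dimers = 5L, n_frames = 1L)
  b <- build_stack(p)
  dir <- withr::local_tempdir()
  write_topology_json(b$topology, file.path(dir, "t.json"))
  ann <- jsonlite::read_json(file.path(dir, "t.json"))
  ann$axis_order <- NULL
  traj <- stack_trajectory(array(b$coords0, c(nrow(b$coords0), 3, 1)), 0, b$box)
  write_trajectory_xyz(traj, file.path(dir, "frame0.xyz"))
  topo <- load_topology(file.path(dir, "frame0.xyz"), ann)
  ord <- topo$axis_order$S1
  expect_true(identical(ord, 1:5) || identical(ord, 5:1))
})

test_that("tip labelling counts terminal dimers and is end-symmetric", {
  p <- synthetic_params(n_dimers = 20L, n_frames = 1L)
  topo <- build_stack(p)$topology
  l1 <- label_tips(topo, 1L)
  expect_equal(sum(l1 == "tip"), 4L)
  expect_equal(sum(l1 == "backbone"), 36L)
  expect_equal(sum(label_tips(topo, 2L) == "tip"), 8L)
  expect_error(label_tips(topo, 11L), "out of bounds")
  expect_error(label_tips(topo, 0L), "out of bounds")

  # a 2-dimer stack has no backbone: all four monomers are formally tips
  topo2 <- build_stack(synthetic_params(n_dimers = 2L, n_frames = 1L))$topology
  expect_true(all(label_tips(topo2, 1L) == "tip"))

  # reversing the axis order leaves the labels unchanged
  rev_topo <- topo
  rev_topo$axis_order$S1 <- rev(topo$axis_order$S1)
  expect_equal(label_tips(rev_topo, 2L), label_tips(topo, 2L))
})

test_that("trajectory XYZ round-trip preserves coordinates, times and box", {
  set.seed(4)
  coords <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  traj <- stack_trajectory(coords, times = c(0, 2.5, 5, 7.5), box = c(8, 9, 10))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, f, digits = 8)
  back <- read_trajectory(f)
  expect_equal(back$coords, traj$coords, tolerance = 1e-7)
  expect_equal(back$times, traj$times)
  expect_equal(back$box[1, ], c(8, 9, 10))
  expect_equal(back$dt_frame, 2.5)

  # stride on read
  strided <- read_trajectory(f, stride = 2L)
  expect_equal(dim(strided$coords)[3], 2L)
  expect_equal(strided$dt_frame, 5)

  # selection on read
  sel <- read_trajectory(f, selection = c(1L, 3L))
  expect_equal(dim(sel$coords)[1], 2L)
  expect_equal(sel$coords[2, , ], traj$coords[3, , ], tolerance = 1e-7)
})

test_that("trajectory reader rejects truncated and inconsistent input", {
  set.seed(5)
  traj <- stack_trajectory(array(rnorm(36), c(3, 3, 4)), 0:3, c(5, 5, 5))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, f)
  lines <- readLines(f)
  writeLines(lines[1:(length(lines) - 2)], f)   # chop mid-frame
  expect_error(read_trajectory(f), "truncated")
  writeLines(lines, f)
  expect_error(read_trajectory(f, n_atoms = 7L), "mismatch")
  expect_error(read_trajectory("x.xtc"), "XTC")
  # non-uniform sampling is a hard error naming the frame
  expect_error(stack_trajectory(array(rnorm(36), c(3, 3, 4)),
                                c(0, 1, 2, 3.5), c(5, 5, 5)),
               "non-uniform")
})

test_that("bias trace reader computes beta and enforces the contract", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#! FIELDS time cv1 bias ct",
               "0.0 1.0 0.0 0.0",
               "10.0 1.1 2.0 0.5",
               "20.0 1.3 3.5 0.9"), f)
  tr <- read_bias_trace(f, temperature = 298,
                        column_map = list(time = "time", bias = "bias", ct = "ct"))
  expect_equal(tr$beta, 1 / (0.0083144621 * 298), tolerance = 1e-12)
  expect_equal(tr$c_t, c(0, 0.5, 0.9))
  expect_equal(names(tr$cvs), "cv1")

  # unsorted rows: sorted with a warning
  writeLines(c("time bias", "10 1.0", "0 0.0", "20 2.0"), f)
  expect_warning(tr2 <- read_bias_trace(f), "sort")
  expect_equal(tr2$time, c(0, 10, 20))
  expect_equal(tr2$bias, c(0, 1, 2))

  writeLines(c("time cv", "0 1", "10 2"), f)
  expect_error(read_bias_trace(f), "bias")
  writeLines(c("time bias", "0 1", "x 2"), f)
  expect_error(read_bias_trace(f), "line 2")
})

test_that("beta is strictly decreasing in temperature", {
  temps <- seq(200, 400, by = 10)
  expect_true(all(diff(beta_from_temperature(temps)) < 0))
})
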