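test_that("identical or rigidly moved frames give an all-zero trace", {
  set.seed(43)
  xyz <- matrix(rnorm(36, sd = 4), 12)
  still <- trajectory(toy_structure(xyz), list(xyz, xyz, xyz), dt = 10)
  expect_close(rmsd_trace(still)$values, rep(0, 3), 1e-9)

  moved <- trajectory(toy_structure(xyz),
                      lapply(1:4, function(i) rigid_transform(xyz)),
                      dt = 10)
  expect_close(rmsd_trace(moved)$values, rep(0, 4), 1e-7)
})

test_that("trace values match hand-computed displacements", {
  # 2 fit atoms fixed at origin-ish, one measured atom displaced by d
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(5, 5, 0))
  d <- c(0, 0.5, 1.2, 2.0, 3.3)
  frames <- lapply(d, function(dd) {
    f <- xyz; f[4, 3] <- dd; f
  })
  tr <- trajectory(toy_structure(xyz), frames)
  trace <- rmsd_trace(tr, ref = 1, fit_sel = 1:3, measure_sel = 4)
  expect_close(trace$values, d, 1e-9)
})

test_that("analysis windows cut by time correctly", {
  xyz <- matrix(rnorm(9), 3)
  tr <- trajectory(toy_structure(xyz),
                   replicate(1000, xyz, simplify = FALSE), dt = 10)
  # 10 ns saved every 10 ps; dropping the first 3 ns leaves 7 ns
  w <- analysis_window(tr, 3000)
  expect_equal(n_frames(w), 700)
  expect_equal(frame_times(w)[1], 3000)
  expect_equal(n_frames(analysis_window(tr, 0)), 1000)
  expect_equal(n_frames(analysis_window(tr, 9990)), 1)
  expect_error(analysis_window(tr, 1e6), "window error")
})

test_that("identical frames collapse to one cluster", {
  xyz <- matrix(rnorm(48, sd = 4), 16)
  tr <- trajectory(toy_structure(xyz, name = "CA"),
                   replicate(5, xyz, simplify = FALSE))
  cs <- cluster_conformers(tr, sel = "name CA", radius = 2)
  expect_equal(length(cs$sizes), 1)
  expect_equal(cs$sizes, 5)
})

test_that("planted conformer ensembles are recovered exactly", {
  for (k in c(2, 5)) {
    gen <- make_conformer_ensemble(k = k, sizes = 6, intra_sigma = 0.2,
                                   separation = 6, seed = 7 + k)
    cs <- cluster_conformers(gen$trajectory, radius = 2)
    expect_equal(length(cs$sizes), k)
    # planted labels and recovered labels agree up to relabelling
    expect_equal(length(unique(paste(gen$labels, cs$assignments))), k)
  }
})

test_that("the cluster radius boundary is inclusive", {
  # two frames whose main-chain RMSD is exactly 2.0 after fitting
  xyz <- cbind(seq(0, 45, by = 3), 0, 0)  # 16 collinear? no - bend it
  xyz[, 2] <- rep(c(0, 2), 8)
  f2 <- xyz; f2[, 3] <- f2[, 3] + 2.0     # uniform 2.0 A displacement...
  # a uniform translation fits away; displace alternating atoms instead
  f2 <- xyz; f2[seq(1, 16, 2), 3] <- 2.0 * sqrt(2)
  tr <- trajectory(toy_structure(xyz, name = "CA"), list(xyz, f2))
  r <- kabsch_superpose(tr$frames[[2]], tr$frames[[1]])$rmsd
  cs_in <- cluster_conformers(tr, sel = "name CA", radius = r + 1e-6)
  expect_equal(length(cs_in$sizes), 1)
  cs_out <- cluster_conformers(tr, sel = "name CA", radius = r - 1e-3)
  expect_equal(length(cs_out$sizes), 2)
})

test_that("cluster count is non-increasing in radius and deterministic", {
  gen <- make_conformer_ensemble(k = 4, sizes = 5, intra_sigma = 0.3,
                                 separation = 8, seed = 53)
  prev <- Inf
  for (r in c(0.5, 1, 2, 4, 16)) {
    k <- length(cluster_conformers(gen$trajectory, radius = r)$sizes)
    expect_lte(k, prev)
    prev <- k
  }
  a <- cluster_conformers(gen$trajectory, radius = 2)
  b <- cluster_conformers(gen$trajectory, radius = 2)
  expect_identical(a$assignments, b$assignments)
})

test_that("every frame lies within the radius of its representative", {
  gen <- make_conformer_ensemble(k = 3, sizes = 7, intra_sigma = 0.25,
                                 separation = 7, seed = 59)
  tr <- gen$trajectory
  cs <- cluster_conformers(tr, radius = 2)
  idx <- select_atoms(tr, "mainchain")
  for (f in seq_along(cs$assignments)) {
    rep_f <- cs$representatives[cs$assignments[f]]
    expect_lte(kabsch_superpose(tr$frames[[f]], tr$frames[[rep_f]],
                                idx)$rmsd, 2 + 1e-9)
  }
})

test_that("grid boxes sit at the centre of gravity", {
  s1 <- toy_structure(matrix(c(1, 2, 3), 1))
  expect_equal(grid_box(s1)$center, c(1, 2, 3))

  s2 <- toy_structure(rbind(c(-5, 0, 0), c(5, 0, 0)))
  expect_equal(grid_box(s2)$center, c(0, 0, 0))

  # hand-computed mass-weighted mean for C, N, O, S at unit points
  atoms <- toy_atoms(4, element = c("C", "N", "O", "S"))
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  w <- c(12.011, 14.007, 15.999, 32.06)
  expect_equal(grid_box(structure3d(atoms, xyz))$center,
               colSums(xyz * w) / sum(w))
  # hydrogens never contribute
  atoms_h <- toy_atoms(2, element = c("C", "H"))
  sh <- structure3d(atoms_h, rbind(c(2, 2, 2), c(9, 9, 9)))
  expect_equal(grid_box(sh)$center, c(2, 2, 2))

  cfg <- write_vina_config(grid_box(s1))
  expect_match(cfg[1], "center_x = 1.000")
  expect_match(cfg[4], "size_x = 40")
  expect_error(grid_box(s1, edge = 40, spacing = 50), "spacing")
})
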