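toy_pose <- function(xyz, score = -8, element = rep("C", nrow(xyz)),
                     id = "cpd", conf = 1L) {
  list(compound_id = id, conformer_id = conf, score = score,
       element = element, name = paste0(element, seq_len(nrow(xyz))),
       xyz = as.matrix(xyz))
}
as_pose_set <- function(...) structure(list(...), class = "pose_set")

test_that("pose files round-trip scores and coordinates", {
  set.seed(73)
  p1 <- toy_pose(matrix(round(rnorm(9, sd = 4), 3), 3), score = -7.3,
                 element = c("C", "N", "O"))
  p2 <- toy_pose(matrix(round(rnorm(9, sd = 4), 3), 3), score = -6.1,
                 element = c("C", "C", "Cl"))
  f <- withr::local_tempfile(fileext = ".pdbqt")
  write_vina_poses(as_pose_set(p1, p2), f)
  back <- read_vina_poses(f, compound_id = "cpd")
  expect_length(back, 2)
  expect_equal(back[[1]]$score, -7.3)  # sorted best first
  expect_equal(back[[2]]$score, -6.1)
  expect_close(back[[1]]$xyz, p1$xyz, 5e-4)
  expect_equal(back[[1]]$element, p1$element)
})

test_that("malformed pose files raise errors naming the model", {
  p <- toy_pose(matrix(rnorm(6), 2), score = -7)
  f <- withr::local_tempfile(fileext = ".pdbqt")
  write_vina_poses(as_pose_set(p, p), f)
  lines <- readLines(f)
  # remove the remark from model 2 only
  lines2 <- lines[-(grep("VINA RESULT", lines)[2])]
  writeLines(lines2, f)
  expect_error(read_vina_poses(f), "model 2")
  writeLines("REMARK nothing", f)
  expect_error(read_vina_poses(f), "empty-file")
})

test_that("hydrogens are dropped when reading PDBQT", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:    -7.500      0.000      0.000",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C ",
    "ATOM      2  H1  LIG A   1       1.000   0.000   0.000  1.00  0.00     0.000 HD",
    "ATOM      3  O1  LIG A   1       2.000   0.000   0.000  1.00  0.00     0.000 OA",
    "ENDMDL"), f)
  p <- read_vina_poses(f)
  expect_equal(nrow(p[[1]]$xyz), 2)
  expect_equal(p[[1]]$element, c("C", "O"))
})

test_that("pose clustering separates planted position clusters", {
  set.seed(79)
  base <- matrix(rnorm(12, sd = 2), 4)
  near <- lapply(1:10, function(i)
    toy_pose(base + matrix(rnorm(12, sd = 0.1), 4), score = -7 - 0.1 * i))
  cl <- cluster_poses(do.call(as_pose_set, near), radius = 2)
  expect_equal(attr(cl, "n_clusters"), 1)

  twoA <- toy_pose(base, -8); twoB <- toy_pose(base + 10, -7.5)
  cl2 <- cluster_poses(as_pose_set(twoA, twoB), radius = 2)
  expect_equal(attr(cl2, "n_clusters"), 2)

  planted <- c(lapply(1:3, function(i)
    toy_pose(base + matrix(rnorm(12, sd = 0.2), 4), score = -8 + 0.1 * i)),
    lapply(1:3, function(i)
      toy_pose(base + 12 + matrix(rnorm(12, sd = 0.2), 4),
               score = -7 + 0.1 * i)),
    lapply(1:2, function(i)
      toy_pose(base - 12 + matrix(rnorm(12, sd = 0.2), 4),
               score = -6 + 0.1 * i)))
  cl3 <- cluster_poses(do.call(as_pose_set, planted), radius = 2)
  expect_equal(attr(cl3, "n_clusters"), 3)
  expect_equal(cl3, c(1, 1, 1, 2, 2, 2, 3, 3), ignore_attr = TRUE)
})

test_that("growing the cluster radius never adds clusters", {
  set.seed(83)
  poses <- do.call(as_pose_set, lapply(1:12, function(i)
    toy_pose(matrix(rnorm(9, sd = 4), 3), score = -7 - 0.05 * i)))
  prev <- Inf
  for (r in c(0.5, 1, 2, 5, 20)) {
    k <- attr(cluster_poses(poses, r), "n_clusters")
    expect_lte(k, prev); prev <- k
  }
})

test_that("pose contact typing matches hand enumeration", {
  rec <- make_toy_receptor(n_residues = 5)
  # ligand O at 3.2 A below residue-1 N; no carbons near anything
  p <- toy_pose(rbind(c(12, -3.2, 0), c(12, -40, 0)),
                element = c("O", "C"))
  cc <- pose_contacts(p, rec, "all")
  expect_equal(cc$n_polar, 1)
  expect_equal(cc$n_hydrophobic, 0)
  expect_equal(cc$residues$key, "R:771:ALA")

  far <- toy_pose(matrix(100, 2, 3), element = c("O", "C"))
  ccf <- pose_contacts(far, rec, "all")
  expect_equal(ccf$n_polar + ccf$n_hydrophobic, 0)

  # brute-force oracle over all (ligand atom, residue) pairs
  set.seed(89)
  lig <- toy_pose(cbind(runif(8, 0, 60), runif(8, -5, 8), runif(8, -3, 3)),
                  element = sample(c("C", "N", "O"), 8, TRUE))
  crit <- triage_criteria()
  got <- pose_contacts(lig, rec, "all", crit)
  n_pol <- 0; n_hyd <- 0
  for (i in 1:8) for (r in unique(rec$atoms$resid)) {
    ri <- which(rec$atoms$resid == r)
    dmin <- function(keep) if (!length(keep)) Inf else
      min(sqrt(colSums((t(rec$xyz[keep, , drop = FALSE]) - lig$xyz[i, ])^2)))
    if (lig$element[i] %in% c("N", "O") &&
        dmin(ri[rec$atoms$element[ri] %in% c("N", "O")]) <=
          crit$polar_cutoff) n_pol <- n_pol + 1
    if (lig$element[i] == "C" &&
        dmin(ri[rec$atoms$element[ri] == "C"]) <=
          crit$hydrophobic_cutoff) n_hyd <- n_hyd + 1
  }
  expect_equal(got$n_polar, n_pol)
  expect_equal(got$n_hydrophobic, n_hyd)
})

test_that("the verdict truth table covers all boundary combinations", {
  rec <- make_toy_receptor()
  crit <- triage_criteria()
  mk_set <- function(score, two_clusters, with_contacts) {
    xyz <- if (with_contacts) rbind(c(12, -3.2, 0), c(12, 6.5, 0))
           else rbind(c(12, -40, 0), c(12, 40, 0))
    main <- toy_pose(xyz, score = score, element = c("O", "C"))
    second <- toy_pose(xyz + if (two_clusters) 15 else 0.1,
                       score = score + 0.5, element = c("O", "C"))
    as_pose_set(main, second)
  }
  cases <- expand.grid(score = c(-7.0, -6.9), two = c(FALSE, TRUE),
                       contacts = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    hits <- select_hits(list(mk_set(cs$score, cs$two, cs$contacts)),
                        rec, "all", crit)
    expect_equal(hits$verdict,
                 cs$score <= -7.0 && !cs$two && cs$contacts,
                 info = paste(cs$score, cs$two, cs$contacts))
  }
  # exactly -7.0 with one cluster and both contacts passes (inclusive)
  ok <- select_hits(list(mk_set(-7.0, FALSE, TRUE)), rec, "all", crit)
  expect_true(ok$verdict)
  bad <- select_hits(list(mk_set(-8.5, TRUE, TRUE)), rec, "all", crit)
  expect_false(bad$verdict)
  expect_match(bad$reasons, "multiple clusters")
})

test_that("the representative is the best pose across conformers", {
  rec <- make_toy_receptor()
  xyz <- rbind(c(12, -3.2, 0), c(12, 6.5, 0))
  sets <- lapply(1:3, function(conf) as_pose_set(
    toy_pose(xyz, score = -6 - conf * 0.5, element = c("O", "C"),
             conf = conf),
    toy_pose(xyz + 0.05, score = -5.5 - conf * 0.5,
             element = c("O", "C"), conf = conf)))
  hits <- select_hits(sets, rec, "all")
  expect_equal(hits$best_score, -7.5)
  expect_equal(hits$best_conformer, "3")
  expect_true(hits$verdict)
})
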