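# Run code under a fixed RNG seed without disturbing the caller's RNG
# stream. Every generator takes a mandatory seed and is a pure function
# of (spec, seed).
.with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory for every generator")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

.clamp <- function(x, a) pmin(pmax(x, -a), a)

.jitter_mat <- function(n, sigma, clamp = 2 * sigma) {
  matrix(.clamp(stats::rnorm(n * 3, 0, sigma), clamp), ncol = 3)
}

#' Generate a trajectory with planted residue-pair contact persistence
#'
#' Two chains (A, B) of single-heavy-atom residues on a wide lattice.
#' In each frame, planted pair i is placed in contact (distance in
#' [2.2, 2.6] A, i.e. within the 3 A cutoff) with independent Bernoulli
#' probability equal to its target fraction, otherwise well outside it
#' (> 6 A). Decoy residues sit > 10 A from everything. Coordinates get
#' truncated Gaussian jitter small enough never to move a pair across
#' the contact boundary, so the per-frame realizations recorded in the
#' ground truth are exact.
#'
#' @param target_fractions Numeric vector of target persistence fractions
#'   in [0, 1], one planted pair each.
#' @param n_frames Number of frames.
#' @param seed RNG seed (mandatory).
#' @param jitter Coordinate jitter sigma in Angstrom (must stay below
#'   ~0.057 so the contact bands cannot be crossed).
#' @param n_decoy Far-placed decoy residues per chain.
#' @param dt Frame spacing metadata in ps.
#' @param dir Optional directory: writes `trajectory.pdb`,
#'   `ground_truth.tsv` and `realizations.tsv` there.
#' @return List: `trajectory`, `truth` (pair keys, target and realized
#'   fractions), `realizations` (frames x pairs logical matrix).
#' @export
make_contact_trajectory <- function(target_fractions, n_frames = 100,
                                    seed, jitter = 0.05, n_decoy = 2,
                                    dt = 10, dir = NULL) {
  stopifnot(all(target_fractions >= 0 & target_fractions <= 1),
            n_frames >= 1)
  clamp <- 2 * jitter * sqrt(3)
  if (2.6 + 2 * clamp >= 3.0 || 6.5 - 2 * clamp <= 6.0)
    stop("spec error: jitter too large for the planted contact bands")
  k <- length(target_fractions)
  .with_seed(seed, {
    # topology: chain A residue i at x = 40 i; partner B residue opposite
    mk_atoms <- function(chain, resids, names) data.frame(
      serial = seq_along(resids), name = names, element = "C",
      resname = "GLY", resid = resids, chain = chain, occupancy = 1,
      bfactor = 0)
    atomsA <- mk_atoms("A", seq_len(k), "CA")
    atomsB <- mk_atoms("B", seq_len(k), "CA")
    dec <- if (n_decoy > 0) rbind(
      mk_atoms("A", k + seq_len(n_decoy), "CA"),
      mk_atoms("B", k + seq_len(n_decoy), "CA")) else NULL
    atoms <- rbind(atomsA, atomsB, dec)
    atoms$serial <- seq_len(nrow(atoms))
    baseA <- cbind(40 * seq_len(k), 0, 0)
    base_dec <- if (n_decoy > 0)
      cbind(40 * rep(seq_len(n_decoy), 2), rep(c(60, 90), each = n_decoy), 0)
    realiz <- matrix(FALSE, n_frames, k)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      inc <- stats::runif(k) < target_fractions
      realiz[f, ] <- inc
      dAB <- ifelse(inc, stats::runif(k, 2.2, 2.6), stats::runif(k, 6.5, 8.0))
      xyz <- rbind(baseA, baseA + cbind(0, dAB, 0), base_dec)
      frames[[f]] <- xyz + .jitter_mat(nrow(xyz), jitter)
    }
    topo <- structure3d(atoms, frames[[1]], id = "planted_contacts")
    traj <- trajectory(topo, frames, dt = dt)
    truth <- data.frame(
      key_a = paste("A", seq_len(k), "GLY", sep = ":"),
      key_b = paste("B", seq_len(k), "GLY", sep = ":"),
      target_fraction = target_fractions,
      realized_fraction = colMeans(realiz))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_multimodel_pdb(traj, file.path(dir, "trajectory.pdb"))
      utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(realiz * 1L, file.path(dir, "realizations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(trajectory = traj, truth = truth, realizations = realiz)
  })
}

#' Generate a conformer ensemble with planted cluster structure
#'
#' A toy main-chain (N, CA, C, O per residue) is deformed into k cluster
#' centres whose pairwise superposed RMSD is set by `separation`; each
#' frame is its cluster centre plus Gaussian jitter `intra_sigma`, and
#' frame order is a seeded shuffle. Recovery by leader clustering at
#' `check_radius` is guaranteed when the realized centre separation
#' exceeds 2 * (check_radius + 3 * intra_sigma); a spec warning is
#' emitted otherwise.
#'
#' @param k Number of planted clusters.
#' @param sizes Frames per cluster (scalar or length-k vector).
#' @param intra_sigma Within-cluster jitter sigma (A).
#' @param separation Target pairwise centre RMSD (A).
#' @param seed RNG seed (mandatory).
#' @param n_residues Main-chain residues of the toy backbone.
#' @param check_radius Cluster radius the recoverability condition is
#'   checked against.
#' @param dir Optional directory for `ensemble.pdb` + `labels.tsv`.
#' @return List: `trajectory`, `labels` (planted cluster per frame),
#'   `centre_rmsd` (k x k realized matrix).
#' @export
make_conformer_ensemble <- function(k, sizes = 10, intra_sigma = 0.2,
                                    separation = 6, seed, n_residues = 12,
                                    check_radius = 2.0, dir = NULL) {
  stopifnot(k >= 1, all(sizes >= 1))
  if (length(sizes) == 1) sizes <- rep(sizes, k)
  stopifnot(length(sizes) == k)
  .with_seed(seed, {
    bb_names <- c("N", "CA", "C", "O")
    n_at <- 4 * n_residues
    atoms <- data.frame(
      serial = seq_len(n_at), name = rep(bb_names, n_residues),
      element = rep(c("N", "C", "C", "O"), n_residues),
      resname = "ALA", resid = rep(seq_len(n_residues), each = 4),
      chain = "C", occupancy = 1, bfactor = 0)
    base <- cbind(rep(3.8 * seq_len(n_residues), each = 4) +
                    rep(c(0, 1.2, 2.4, 2.4), n_residues),
                  rep(c(0, 1.0, 0.4, 1.6), n_residues),
                  rep(c(0, 0.2, 0.8, 2.0), n_residues))
    defs <- lapply(seq_len(k), function(j)
      if (j == 1) matrix(0, n_at, 3) else
        matrix(stats::rnorm(n_at * 3, 0, separation / sqrt(6)), ncol = 3))
    pair_min <- function(centres) {
      m <- Inf
      for (i in 1:(k - 1)) for (j in (i + 1):k)
        m <- min(m, kabsch_superpose(centres[[i]], centres[[j]])$rmsd)
      m
    }
    centres <- lapply(defs, function(d) base + d)
    if (k > 1) {
      # superposition shrinks raw deviation norms; rescale the planted
      # deformations until the smallest pairwise centre RMSD hits target
      for (it in 1:4) {
        cur <- pair_min(centres)
        if (abs(cur - separation) < 0.05 * separation) break
        defs <- lapply(defs, function(d) d * separation / cur)
        centres <- lapply(defs, function(d) base + d)
      }
    }
    crmsd <- matrix(0, k, k)
    if (k > 1)
      for (i in 1:(k - 1)) for (j in (i + 1):k)
        crmsd[i, j] <- crmsd[j, i] <-
          kabsch_superpose(centres[[i]], centres[[j]])$rmsd
    if (k > 1 && min(crmsd[upper.tri(crmsd)]) <=
        2 * (check_radius + 3 * intra_sigma))
      warning("spec warning: planted centre separation below ",
              "2*(radius + 3*sigma); recovery not guaranteed")
    labels <- rep(seq_len(k), sizes)
    ord <- sample(length(labels))
    labels <- labels[ord]
    frames <- lapply(labels, function(j)
      centres[[j]] + matrix(stats::rnorm(n_at * 3, 0, intra_sigma),
                            ncol = 3))
    topo <- structure3d(atoms, frames[[1]], id = "planted_ensemble")
    traj <- trajectory(topo, frames, dt = 10)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_multimodel_pdb(traj, file.path(dir, "ensemble.pdb"))
      utils::write.table(
        data.frame(frame = seq_along(labels), cluster = labels),
        file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    list(trajectory = traj, labels = labels, centre_rmsd = crmsd)
  })
}

#' Toy binding-site receptor for pose campaigns
#'
#' A single-chain pocket of residues 12 A apart, each with one backbone
#' nitrogen (polar) and one carbon (hydrophobic), numbered from
#' `first_resid` (clamp-style numbering by default).
#'
#' @param n_residues Number of site residues.
#' @param first_resid First author residue number.
#' @return A [structure3d].
#' @export
make_toy_receptor <- function(n_residues = 5, first_resid = 771) {
  resid <- first_resid + seq_len(n_residues) - 1
  atoms <- data.frame(
    serial = seq_len(2 * n_residues),
    name = rep(c("N", "CA"), n_residues),
    element = rep(c("N", "C"), n_residues),
    resname = "ALA", resid = rep(resid, each = 2), chain = "R",
    occupancy = 1, bfactor = 0)
  xyz <- cbind(rep(12 * seq_len(n_residues), each = 2),
               rep(c(0, 3), n_residues), 0)
  structure3d(atoms, xyz, id = "toy_receptor")
}

#' Specification table for a synthetic docking campaign
#'
#' Draws per-compound planted outcomes: best score, pose-cluster count,
#' polar/hydrophobic contact counts of the best pose, stability class
#' (the 3/2/1 RMSD score the stability stage must recover), persistent
#' contact flag and a binding energy. Exactly `n_triage_pass` compounds
#' pass the default triage rule and exactly `n_gate_pass` of those pass
#' the stability gate (>= 1 persistent contact and RMSD score >= 2).
#'
#' @param n_compounds Campaign size.
#' @param n_triage_pass Planted triage passes.
#' @param n_gate_pass Planted stability-gate passes (among the triage
#'   passes).
#' @param seed RNG seed (mandatory).
#' @return data.frame, one row per compound.
#' @export
campaign_spec <- function(n_compounds = 29, n_triage_pass = 29,
                          n_gate_pass = 11, seed) {
  stopifnot(n_gate_pass <= n_triage_pass, n_triage_pass <= n_compounds)
  .with_seed(seed, {
    id <- sprintf("cpd%03d", seq_len(n_compounds))
    tri <- seq_len(n_compounds) <= n_triage_pass
    gate <- seq_len(n_compounds) <= n_gate_pass
    best_score <- ifelse(tri, round(stats::runif(n_compounds, -9.5, -7.0), 1),
                         round(stats::runif(n_compounds, -6.9, -5.0), 1))
    n_clusters <- ifelse(tri, 1L, sample(1:3, n_compounds, TRUE))
    # a failing compound must fail at least one criterion; force clusters
    # to 1 for score-failures only, and let some score-passers fail on
    # clustering in larger campaigns
    n_polar <- ifelse(tri, sample(1:3, n_compounds, TRUE),
                      sample(0:3, n_compounds, TRUE))
    n_hydrophobic <- ifelse(tri, sample(1:3, n_compounds, TRUE),
                            sample(0:3, n_compounds, TRUE))
    stability_class <- ifelse(gate, sample(2:3, n_compounds, TRUE), 1L)
    has_persistent <- gate
    # non-gate compounds split between unstable and contact-free
    flip <- !gate & (stats::runif(n_compounds) < 0.5)
    stability_class[flip] <- sample(2:3, sum(flip), TRUE)
    has_persistent[flip] <- FALSE
    energy <- round(stats::runif(n_compounds, -45, -10), 1)
    spec <- data.frame(
      compound_id = id, best_score = best_score,
      n_pose_clusters = n_clusters, n_polar = n_polar,
      n_hydrophobic = n_hydrophobic, stability_class = stability_class,
      has_persistent_contact = has_persistent,
      energy_kcal_mol = energy)
    spec[sample(n_compounds), , drop = FALSE]
  })
}

.plant_best_pose <- function(receptor, n_polar, n_hydrophobic) {
  if (n_polar > 3 || n_hydrophobic > 3)
    stop("spec error: at most 3 planted contacts of each type")
  rx <- 12 * seq_len(3)
  xyz <- matrix(0, 6, 3)
  el <- c("O", "O", "O", "C", "C", "C")
  nm <- c("O1", "O2", "O3", "C1", "C2", "C3")
  for (i in 1:3) {
    xyz[i, ] <- if (i <= n_polar) c(rx[i], -3.2, 0) else c(rx[i], 40, 0)
    xyz[3 + i, ] <- if (i <= n_hydrophobic) c(rx[i], 6.5, 0)
                    else c(rx[i], 40, 8)
  }
  list(element = el, name = nm, xyz = xyz)
}

#' Generate a synthetic docking campaign with planted verdicts
#'
#' Writes one Vina-dialect PDBQT per compound realizing the planted
#' best score, position-cluster layout and best-pose contact counts of
#' `spec`, plus an energy table and the verdict each compound must
#' receive under default [triage_criteria()]. Contradictions in the
#' spec (e.g. contact counts above what the toy site can hold) are
#' errors.
#'
#' @param spec data.frame from [campaign_spec()].
#' @param receptor A [structure3d] from [make_toy_receptor()] (>= 3
#'   residues).
#' @param seed RNG seed (mandatory).
#' @param n_poses Poses per compound (>= n_pose_clusters).
#' @param dir Optional directory: writes `<id>.pdbqt`, `energies.tsv`,
#'   `verdicts.tsv`.
#' @return List: `posesets` (list of pose_set), `energies`,
#'   `verdicts` (data.frame compound_id, expect_pass), `spec`.
#' @export
make_pose_campaign <- function(spec, receptor = make_toy_receptor(),
                               seed, n_poses = 8, dir = NULL) {
  crit <- triage_criteria()
  .with_seed(seed, {
    posesets <- vector("list", nrow(spec))
    for (i in seq_len(nrow(spec))) {
      s <- spec[i, ]
      if (n_poses < s$n_pose_clusters)
        stop("spec error: fewer poses than planted clusters")
      best <- .plant_best_pose(receptor, s$n_polar, s$n_hydrophobic)
      poses <- vector("list", n_poses)
      cluster_of <- c(seq_len(s$n_pose_clusters),
                      sample(seq_len(s$n_pose_clusters),
                             n_poses - s$n_pose_clusters, TRUE))
      for (p in seq_len(n_poses)) {
        shift <- if (cluster_of[p] == 1) c(0, 0, 0)
                 else c(0, -15 * (cluster_of[p] - 1), 10)
        jit <- if (p == 1) 0 else .jitter_mat(6, 0.08)
        poses[[p]] <- list(
          compound_id = s$compound_id, conformer_id = 1L,
          score = s$best_score + 0.3 * (p - 1),
          element = best$element, name = best$name,
          xyz = sweep(best$xyz, 2, -shift) + jit)
      }
      class(poses) <- "pose_set"
      posesets[[i]] <- poses
    }
    names(posesets) <- spec$compound_id
    energies <- data.frame(compound_id = spec$compound_id,
                           energy_kcal_mol = spec$energy_kcal_mol,
                           method = "planted")
    verdicts <- data.frame(
      compound_id = spec$compound_id,
      expect_pass = spec$best_score <= crit$score_max &
        spec$n_pose_clusters == 1 &
        spec$n_polar >= crit$min_polar &
        spec$n_hydrophobic >= crit$min_hydrophobic)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(posesets))
        write_vina_poses(posesets[[i]],
                         file.path(dir, paste0(spec$compound_id[i],
                                               ".pdbqt")))
      utils::write.table(energies, file.path(dir, "energies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(verdicts, file.path(dir, "verdicts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(posesets = posesets, energies = energies, verdicts = verdicts,
         spec = spec)
  })
}

#' Generate a planted ligand-stability trajectory for one compound
#'
#' Complex trajectory of the toy receptor plus a 6-atom ligand whose
#' dynamics realize a planted stability class: class 3 jitters in place
#' (single mode, small RMSD), class 2 wobbles around one mode (single
#' mode, mean RMSD above the stable threshold), class 1 hops between two
#' sites 6 A apart (two modes). A planted persistent contact keeps one
#' ligand oxygen within the 3 A cutoff of the first site residue in
#' every frame; without it the contact is broken in half the frames.
#'
#' @param stability_class Planted class in {1, 2, 3}.
#' @param has_persistent_contact Plant a 100%-persistent site contact?
#' @param seed RNG seed (mandatory).
#' @param n_frames Frames (even).
#' @param receptor Toy receptor (its first residue hosts the contact).
#' @param dt Frame spacing in ps.
#' @return A complex [trajectory] (receptor chain R + ligand resname LIG).
#' @export
make_stability_trajectory <- function(stability_class,
                                      has_persistent_contact, seed,
                                      n_frames = 20,
                                      receptor = make_toy_receptor(),
                                      dt = 10) {
  stopifnot(stability_class %in% 1:3)
  .with_seed(seed, {
    lig <- .plant_best_pose(receptor, 1, 1)
    lig$xyz[1, ] <- c(12, -2.5, 0)  # O1 vs residue-1 N at (12, 0, 0)
    lat <- data.frame(serial = seq_len(6) + nrow(receptor$atoms),
                      name = lig$name, element = lig$element,
                      resname = "LIG", resid = 1, chain = "L",
                      occupancy = 1, bfactor = 0)
    atoms <- rbind(receptor$atoms, lat)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      lxyz <- lig$xyz
      move <- rep(TRUE, 6)
      if (has_persistent_contact) move[1] <- FALSE
      if (stability_class == 3) {
        lxyz[move, ] <- lxyz[move, ] + .jitter_mat(sum(move), 0.1)
      } else if (stability_class == 2) {
        # frame 1 sits at the mode centre so every later frame stays
        # within the mode radius of the leader seed while the mean
        # displacement exceeds the "very stable" threshold; the shift is
        # calibrated to a 1.7 A ligand RMSD whatever the moving-atom
        # count, leaving margin on both sides (1.5 < rmsd < 2.0) even
        # under worst-case jitter
        ang <- stats::runif(1, 0, 2 * pi)
        amp <- 1.7 * sqrt(6 / sum(move))
        if (f > 1) lxyz[move, ] <- lxyz[move, ] +
          matrix(rep(amp * c(cos(ang), 0, sin(ang)), each = sum(move)),
                 ncol = 3) + .jitter_mat(sum(move), 0.03)
      } else {
        hop <- f > n_frames / 2
        if (hop) lxyz[move, ] <- lxyz[move, ] +
            matrix(rep(c(0, 0, 6), each = sum(move)), ncol = 3)
        lxyz[move, ] <- lxyz[move, ] + .jitter_mat(sum(move), 0.1)
      }
      if (!has_persistent_contact && f %% 2 == 0)
        lxyz[1, ] <- lxyz[1, ] + c(0, -4, 0)  # break the contact
      frames[[f]] <- rbind(receptor$xyz, lxyz) +
        .jitter_mat(nrow(atoms), 0.01)
    }
    topo <- structure3d(atoms, frames[[1]],
                        id = "planted_stability")
    trajectory(topo, frames, dt = dt)
  })
}

# internal catalogue of molecules with frozen rule-violation flags;
# shipped as extdata/catalogue_v1.tsv and verified against an
# independent cheminformatics toolkit in the test suite.
.catalogue <- function() {
  path <- system.file("extdata", "catalogue_v1.tsv", package = "rcscreen")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Generate a small compound library with planted filter outcomes
#'
#' Samples molecules from the packaged descriptor-verified catalogue:
#' `n_compliant` that pass every default filter, planted violators of
#' chosen rules, PAINS and reactive decoys, and spelled-differently
#' duplicates of compliant members. The ground truth gives each
#' molecule's expected violated rules and the per-rule rejection totals
#' the audit must reproduce exactly.
#'
#' @param n_compliant Compliant molecules.
#' @param violators Character vector of rule names to plant one violator
#'   each (may repeat); see the catalogue's `violates` column for the
#'   vocabulary.
#' @param n_duplicates Duplicate spellings to append.
#' @param n_pains,n_reactive Pattern decoys.
#' @param seed RNG seed (mandatory).
#' @param path Optional path to write the SMILES file.
#' @return List: `library` (a `compound_library`), `truth` (id,
#'   violates), `expected` (per-rule rejection counts, n_pass,
#'   n_duplicates).
#' @export
make_library <- function(n_compliant = 5, violators = character(),
                         n_duplicates = 0, n_pains = 0, n_reactive = 0,
                         seed, path = NULL) {
  cat_tab <- .catalogue()
  .with_seed(seed, {
    used <- character()
    pick <- function(pool, n, what) {
      pool <- pool[!(pool$id %in% used), , drop = FALSE]
      if (nrow(pool) < n)
        stop("spec error: catalogue cannot supply ", n, " ", what)
      out <- pool[sample(nrow(pool), n), , drop = FALSE]
      used <<- c(used, out$id)
      out
    }
    comp <- pick(cat_tab[cat_tab$violates == "", ], n_compliant,
                 "compliant molecules")
    vio <- do.call(rbind, lapply(violators, function(r)
      pick(cat_tab[vapply(strsplit(cat_tab$violates, ","), function(v)
        r %in% v, TRUE), ], 1, paste("violator of", r))))
    pai <- pick(cat_tab[grepl("pains", cat_tab$violates), ], n_pains,
                "PAINS decoys")
    rea <- pick(cat_tab[grepl("reactive", cat_tab$violates), ], n_reactive,
                "reactive decoys")
    dup <- if (n_duplicates > 0) {
      # duplicates are alternative spellings of already-picked compliant
      # molecules, so they deliberately reuse rows
      pool <- comp[nzchar(comp$alt_smiles), , drop = FALSE]
      if (nrow(pool) < n_duplicates)
        stop("spec error: not enough duplicate spellings available")
      d <- pool[sample(nrow(pool), n_duplicates), , drop = FALSE]
      data.frame(id = paste0(d$id, "_dup"), smiles = d$alt_smiles,
                 violates = d$violates, alt_smiles = "")
    }
    sel <- rbind(comp[c("id", "smiles", "violates", "alt_smiles")],
                 if (length(violators))
                   vio[c("id", "smiles", "violates", "alt_smiles")],
                 pai[c("id", "smiles", "violates", "alt_smiles")],
                 rea[c("id", "smiles", "violates", "alt_smiles")],
                 if (n_duplicates > 0) dup)
    sel <- sel[sample(nrow(sel)), , drop = FALSE]
    if (anyDuplicated(sel$id)) sel$id <- make.unique(sel$id)
    lines <- paste(sel$smiles, sel$id, sep = "\t")
    if (!is.null(path)) writeLines(lines, path)
    tmp <- tempfile(fileext = ".smi")
    writeLines(lines, tmp)
    lib <- parse_library(tmp)
    unlink(tmp)
    # expected audit totals refer to the deduplicated library: planted
    # duplicate spellings collapse onto their parents before filtering
    uniq <- sel[!grepl("_dup", sel$id), , drop = FALSE]
    rules <- unlist(strsplit(uniq$violates[nzchar(uniq$violates)], ","))
    list(library = lib,
         truth = data.frame(id = sel$id, violates = sel$violates),
         expected = list(rule_counts = table(rules),
                         n_pass = sum(!nzchar(uniq$violates)),
                         n_duplicates = if (n_duplicates > 0)
                           n_duplicates else 0L))
  })
}
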