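# AutoDock atom types -> element symbols (heavy atoms; A = aromatic C).
.adtype_to_element <- function(t) {
  t <- toupper(trimws(t))
  map <- c(C = "C", A = "C", N = "N", NA. = "N", NS = "N", O = "O",
           OA = "O", OS = "O", S = "S", SA = "S", P = "P", F = "F",
           CL = "Cl", BR = "Br", I = "I", MG = "Mg", ZN = "Zn",
           MN = "Mn", CA = "Ca", FE = "Fe")
  names(map)[2] <- "A"; names(map)[4] <- "NA"
  out <- unname(map[t])
  ifelse(is.na(out), .normalise_element(t), out)
}

#' Triage criteria for docking hits
#'
#' The hit-selection rule of the pre-screening stage: a compound passes
#' when its best Vina score is at most `score_max` (affinities are
#' negative; -7 kcal/mol itself passes), its pose group forms a single
#' position cluster, and the best pose makes at least `min_polar` polar
#' and `min_hydrophobic` hydrophobic contacts within the site. Polar
#' contacts pair ligand N/O with receptor N/O within `polar_cutoff`;
#' hydrophobic contacts pair carbons within `hydrophobic_cutoff`.
#'
#' @param score_max Score cutoff in kcal/mol (pass iff score <= this).
#' @param require_single_cluster Demand one position cluster?
#' @param min_polar,min_hydrophobic Minimum contact counts.
#' @param pose_cluster_radius Pose clustering radius in Angstrom.
#' @param polar_cutoff,hydrophobic_cutoff Contact-typing cutoffs (A).
#' @return A `triage_criteria` list.
#' @export
triage_criteria <- function(score_max = -7.0, require_single_cluster = TRUE,
                            min_polar = 1, min_hydrophobic = 1,
                            pose_cluster_radius = 2.0, polar_cutoff = 3.5,
                            hydrophobic_cutoff = 4.0) {
  if (pose_cluster_radius <= 0 || polar_cutoff <= 0 ||
      hydrophobic_cutoff <= 0)
    stop("cutoffs must be positive")
  structure(list(score_max = score_max,
                 require_single_cluster = require_single_cluster,
                 min_polar = min_polar, min_hydrophobic = min_hydrophobic,
                 pose_cluster_radius = pose_cluster_radius,
                 polar_cutoff = polar_cutoff,
                 hydrophobic_cutoff = hydrophobic_cutoff),
            class = "triage_criteria")
}

#' Read docking poses from a Vina-dialect PDBQT file
#'
#' Each MODEL block must carry a "REMARK VINA RESULT:" line whose first
#' number is the predicted affinity (kcal/mol). Only heavy atoms are
#' kept (AutoDock types H/HD/HS are dropped).
#'
#' @param path PDBQT file path.
#' @param compound_id Compound label for the poses.
#' @param conformer_id Receptor conformer the docking ran against.
#' @return A `pose_set`: list of poses, each with `compound_id`,
#'   `conformer_id`, `score` and `xyz`/`atoms` of ligand heavy atoms;
#'   sorted by score ascending (best first).
#' @export
read_vina_poses <- function(path, compound_id = NULL, conformer_id = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(compound_id))
    compound_id <- sub("\\.pdbqt$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) stop("empty-file error: no MODEL blocks in ", path)
  if (length(starts) != length(ends))
    stop("unbalanced MODEL/ENDMDL in ", path)
  poses <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    blk <- lines[starts[m]:ends[m]]
    rem <- grep("^REMARK VINA RESULT:", blk, value = TRUE)
    if (!length(rem))
      stop(sprintf("parse error: model %d of %s lacks a REMARK VINA RESULT line",
                   m, basename(path)))
    score <- suppressWarnings(
      as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "", rem[1])),
                          "\\s+")[[1]][1]))
    if (!is.finite(score))
      stop(sprintf("parse error: unreadable score in model %d of %s",
                   m, basename(path)))
    at <- blk[substr(blk, 1, 6) %in% c("ATOM  ", "HETATM")]
    if (!length(at))
      stop(sprintf("parse error: model %d of %s has no atoms", m,
                   basename(path)))
    adt <- trimws(substr(at, 78, 79))
    heavy <- !(toupper(adt) %in% c("H", "HD", "HS"))
    at <- at[heavy]
    poses[[m]] <- list(
      compound_id = compound_id, conformer_id = conformer_id,
      score = score, model = m,
      element = .adtype_to_element(adt[heavy]),
      name = trimws(substr(at, 13, 16)),
      xyz = cbind(as.numeric(substr(at, 31, 38)),
                  as.numeric(substr(at, 39, 46)),
                  as.numeric(substr(at, 47, 54))))
  }
  poses <- poses[order(vapply(poses, `[[`, 0, "score"))]
  class(poses) <- "pose_set"
  poses
}

#' Cluster poses by position
#'
#' Leader clustering on ligand heavy-atom RMSD in the common receptor
#' frame, with no re-fitting, so a pose that moved across the site lands
#' in a different cluster even when internally identical. The
#' best-scoring pose seeds the first cluster; scanning proceeds in score
#' order, a pose joining the first cluster whose seed lies within
#' `radius` (inclusive).
#'
#' @param poses A `pose_set` (one compound, one receptor conformer).
#' @param radius Cluster radius in Angstrom.
#' @return Integer cluster id per pose (in the pose_set's order), with
#'   attribute `n_clusters`.
#' @export
cluster_poses <- function(poses, radius = 2.0) {
  stopifnot(length(poses) >= 1)
  ord <- order(vapply(poses, `[[`, 0, "score"))
  seeds <- integer(0)
  assign <- integer(length(poses))
  for (p in ord) {
    hit <- 0L
    for (s in seq_along(seeds)) {
      if (coord_rmsd(poses[[p]]$xyz, poses[[seeds[s]]]$xyz) <= radius + 1e-9) {
        hit <- s; break
      }
    }
    if (hit == 0L) { seeds <- c(seeds, p); hit <- length(seeds) }
    assign[p] <- hit
  }
  attr(assign, "n_clusters") <- length(seeds)
  assign
}

#' Contact typing of a pose against a receptor site
#'
#' Counts polar contacts (ligand N/O within `polar_cutoff` of a site N/O)
#' and hydrophobic contacts (ligand C within `hydrophobic_cutoff` of a
#' site C), one count per (ligand atom, site residue) pair, and reports
#' the contacted residues.
#'
#' @param pose One pose from a `pose_set`.
#' @param receptor A [structure3d] in the same frame as the pose.
#' @param site_sel Selection string for the binding-site residues.
#' @param criteria A [triage_criteria()] (for the cutoffs).
#' @return List: n_polar, n_hydrophobic, residues (data.frame key, type).
#' @export
pose_contacts <- function(pose, receptor, site_sel,
                          criteria = triage_criteria()) {
  site <- select_atoms(receptor, site_sel)
  if (!length(site)) stop("selection error: empty site selection")
  rel <- receptor$atoms$element[site]
  rxyz <- receptor$xyz[site, , drop = FALSE]
  count_type <- function(lig_keep, rec_keep, cutoff) {
    li <- which(lig_keep); ri <- which(rec_keep)
    if (!length(li) || !length(ri))
      return(list(n = 0L, keys = character()))
    d2 <- outer(rowSums(pose$xyz[li, , drop = FALSE]^2),
                rowSums(rxyz[ri, , drop = FALSE]^2), "+") -
      2 * tcrossprod(pose$xyz[li, , drop = FALSE],
                     rxyz[ri, , drop = FALSE])
    hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
    if (!nrow(hit)) return(list(n = 0L, keys = character()))
    keys <- .residue_keys(receptor$atoms, site[ri[hit[, 2]]])
    pairs <- unique(paste(li[hit[, 1]], keys))
    list(n = length(pairs), keys = unique(keys))
  }
  pol <- count_type(pose$element %in% c("N", "O"), rel %in% c("N", "O"),
                    criteria$polar_cutoff)
  hyd <- count_type(pose$element == "C", rel == "C",
                    criteria$hydrophobic_cutoff)
  res <- rbind(
    if (length(pol$keys)) data.frame(key = pol$keys, type = "polar"),
    if (length(hyd$keys)) data.frame(key = hyd$keys, type = "hydrophobic"))
  list(n_polar = pol$n, n_hydrophobic = hyd$n,
       residues = res %||% data.frame(key = character(), type = character()))
}

#' Select docking hits across a receptor-conformer ensemble
#'
#' Per compound: the best (lowest) score over all receptor conformers is
#' found; the verdict is pass iff that score is at most the cutoff, the
#' best-scoring conformer's pose group forms a single position cluster,
#' and the best pose makes the required polar and hydrophobic site
#' contacts. The representative is always the lowest-energy pose. Output
#' is sorted by best score ascending.
#'
#' @param posesets List of `pose_set` objects (any compound/conformer
#'   mix; they are regrouped by compound).
#' @param receptors Named list of [structure3d] receptor conformers
#'   (names = conformer ids), or a single structure used for all.
#' @param site_sel Site selection string.
#' @param criteria A [triage_criteria()].
#' @param pooled Cluster poses pooled over all conformers instead of the
#'   best conformer's group only?
#' @return data.frame of hit records: compound_id, best_score,
#'   best_conformer, n_pose_clusters, n_polar, n_hydrophobic, verdict,
#'   reasons.
#' @export
select_hits <- function(posesets, receptors, site_sel,
                        criteria = triage_criteria(), pooled = FALSE) {
  all_poses <- unlist(posesets, recursive = FALSE)
  if (inherits(posesets, "pose_set")) all_poses <- unclass(posesets)
  cmpd <- vapply(all_poses, `[[`, "", "compound_id")
  rows <- lapply(split(seq_along(all_poses), cmpd), function(ii) {
    grp <- all_poses[ii]
    scores <- vapply(grp, `[[`, 0, "score")
    best <- grp[[which.min(scores)]]
    conf <- best$conformer_id
    cl_grp <- if (pooled) grp else
      grp[vapply(grp, function(p)
        identical(p$conformer_id, conf), TRUE)]
    cl_grp <- structure(cl_grp, class = "pose_set")
    ncl <- attr(cluster_poses(cl_grp, criteria$pose_cluster_radius),
                "n_clusters")
    rec <- if (inherits(receptors, "structure3d")) receptors
           else receptors[[as.character(conf)]]
    if (is.null(rec)) stop("no receptor structure for conformer ", conf)
    cc <- pose_contacts(best, rec, site_sel, criteria)
    reasons <- character(0)
    if (!(best$score <= criteria$score_max))
      reasons <- c(reasons, sprintf("score > %g", criteria$score_max))
    if (criteria$require_single_cluster && ncl != 1)
      reasons <- c(reasons, "multiple clusters")
    if (cc$n_polar < criteria$min_polar)
      reasons <- c(reasons, "too few polar contacts")
    if (cc$n_hydrophobic < criteria$min_hydrophobic)
      reasons <- c(reasons, "too few hydrophobic contacts")
    data.frame(compound_id = best$compound_id, best_score = best$score,
               best_conformer = as.character(conf), n_pose_clusters = ncl,
               n_polar = cc$n_polar, n_hydrophobic = cc$n_hydrophobic,
               verdict = !length(reasons),
               reasons = paste(reasons, collapse = "; "))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$best_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write poses as a Vina-dialect PDBQT file
#'
#' MODEL blocks with REMARK VINA RESULT lines; the counterpart of
#' [read_vina_poses()] and the carrier the synthetic campaign generator
#' emits.
#'
#' @param poses A `pose_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vina_poses <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(poses)) {
    p <- poses[[m]]
    writeLines(sprintf("MODEL %d", m), con)
    writeLines(sprintf("REMARK VINA RESULT:    %8.3f      0.000      0.000",
                       p$score), con)
    n <- nrow(p$xyz)
    ad <- ifelse(p$element == "Cl", "Cl",
                 ifelse(p$element == "Br", "Br",
                        ifelse(p$element == "O", "OA",
                               ifelse(p$element == "N", "NA", p$element))))
    writeLines(sprintf(
      "ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00    %6.3f %-2s",
      seq_len(n), p$name, p$xyz[, 1], p$xyz[, 2], p$xyz[, 3],
      0, ad), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Write a hit table as TSV
#' @param hits data.frame from [select_hits()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
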