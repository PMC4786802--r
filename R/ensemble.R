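#' RMSD trace along a trajectory
#'
#' Each frame is superposed onto the reference frame over `fit_sel`
#' (removing overall rotation and translation), then the RMSD is measured
#' over `measure_sel` without re-fitting. With `measure_sel = fit_sel`
#' this is the classical stability trace; with a ligand measure selection
#' and a receptor fit selection it measures ligand drift in the site.
#'
#' @param traj A [trajectory].
#' @param ref Reference frame index.
#' @param fit_sel Selection (string or indices) used for superposition.
#' @param measure_sel Selection measured; defaults to `fit_sel`.
#' @return data.frame `times` (ps, or frame index when dt unset) and
#'   `values` (Angstrom); attributes `reference_frame`, `fit_selection`.
#' @export
rmsd_trace <- function(traj, ref = 1, fit_sel = "heavy",
                       measure_sel = fit_sel) {
  stopifnot(inherits(traj, "trajectory"))
  if (ref < 1 || ref > n_frames(traj)) stop("reference frame out of range")
  fi <- if (is.character(fit_sel)) select_atoms(traj, fit_sel) else fit_sel
  mi <- if (is.character(measure_sel)) select_atoms(traj, measure_sel)
        else measure_sel
  if (!length(fi) || !length(mi)) stop("selection error: empty selection")
  refxyz <- traj$frames[[ref]]
  vals <- vapply(traj$frames, function(f) {
    fit <- kabsch_superpose(f, refxyz, fi)
    sqrt(mean(rowSums((fit$xyz[mi, , drop = FALSE] -
                       refxyz[mi, , drop = FALSE])^2)))
  }, 0)
  out <- data.frame(times = frame_times(traj), values = vals)
  attr(out, "reference_frame") <- ref
  attr(out, "fit_selection") <- fit_sel
  out
}

#' Extract the analysis window of a trajectory
#'
#' Keeps the frames with time >= `t_start` (ps), e.g. dropping the
#' equilibration phase before contact statistics are accumulated.
#'
#' @param traj A [trajectory] with dt metadata (frame indices otherwise).
#' @param t_start Start time in ps (inclusive).
#' @return A [trajectory]; attribute `window_start` records the cut.
#' @export
analysis_window <- function(traj, t_start) {
  tt <- frame_times(traj)
  if (t_start < 0 || t_start > tt[length(tt)])
    stop("window error: t_start outside the trajectory")
  keep <- which(tt >= t_start)
  out <- trajectory(traj$topology, traj$frames[keep], dt = traj$dt,
                    t0 = tt[keep[1]])
  attr(out, "window_start") <- t_start
  out
}

#' Report a plateau onset time from an RMSD trace
#'
#' Helper for choosing an analysis window: returns the first time after
#' which the running mean of the trace changes by less than `tol` over a
#' sliding window of `width` points. Purely advisory; the analysis window
#' itself is always an explicit choice.
#'
#' @param trace data.frame from [rmsd_trace()].
#' @param tol Plateau tolerance in Angstrom.
#' @param width Sliding window width in points.
#' @return Onset time (same units as `trace$times`), or NA if no plateau.
#' @export
equilibration_onset <- function(trace, tol = 0.3, width = 10) {
  v <- trace$values
  if (length(v) <= width) return(NA_real_)
  for (i in seq_len(length(v) - width)) {
    w <- v[i:(i + width)]
    if (max(w) - min(w) < tol) return(trace$times[i])
  }
  NA_real_
}

#' Cluster trajectory frames into main-chain conformers
#'
#' Deterministic leader clustering at a fixed radius: scanning frames in
#' order, a frame joins the first existing cluster whose representative
#' lies within `radius` (main-chain RMSD after pairwise superposition,
#' inclusive boundary), otherwise it founds a new cluster. A final pass
#' re-centres each representative to the cluster medoid (member with the
#' smallest mean RMSD to the others). Clusters are relabelled by
#' decreasing size (ties: founding order).
#'
#' @param traj A [trajectory].
#' @param sel Selection clustered over (default main-chain heavy atoms).
#' @param radius Cluster radius in Angstrom.
#' @return A `conformer_set`: list with `assignments` (frame -> cluster
#'   id), `representatives` (cluster id -> frame index), `sizes`,
#'   `radius`, `sel`.
#' @export
cluster_conformers <- function(traj, sel = "mainchain", radius = 2.0) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- if (is.character(sel)) select_atoms(traj, sel) else sel
  if (!length(idx)) stop("selection error: empty clustering selection")
  nf <- n_frames(traj)
  pair_rmsd <- function(i, j)
    kabsch_superpose(traj$frames[[i]], traj$frames[[j]], idx)$rmsd
  reps <- integer(0)
  assign <- integer(nf)
  for (f in seq_len(nf)) {
    placed <- FALSE
    for (c in seq_along(reps)) {
      if (pair_rmsd(f, reps[c]) <= radius + 1e-9) {
        assign[f] <- c; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, f); assign[f] <- length(reps) }
  }
  # medoid refinement
  for (c in seq_along(reps)) {
    members <- which(assign == c)
    if (length(members) > 2) {
      msum <- vapply(members, function(i)
        mean(vapply(members[members != i], function(j) pair_rmsd(i, j), 0)), 0)
      reps[c] <- members[which.min(msum)]
    }
  }
  sizes <- tabulate(assign, nbins = length(reps))
  ord <- order(-sizes, seq_along(reps))
  relabel <- match(seq_along(reps), ord)
  out <- list(assignments = relabel[assign], representatives = reps[ord],
              sizes = sizes[ord], radius = radius, sel = sel)
  class(out) <- "conformer_set"
  out
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("conformer_set: %d clusters at radius %.2f A; sizes: %s\n",
              length(x$sizes), x$radius,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Export conformer representatives and assignments
#'
#' Writes one PDB per cluster representative plus a TSV of frame
#' assignments.
#'
#' @param cs A `conformer_set`.
#' @param traj The clustered [trajectory].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the assignment TSV path.
#' @export
export_conformers <- function(cs, traj, dir, prefix = "conformer") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (c in seq_along(cs$representatives)) {
    write_multimodel_pdb(get_frame(traj, cs$representatives[c]),
                         file.path(dir, sprintf("%s_%02d.pdb", prefix, c)))
  }
  tsv <- file.path(dir, paste0(prefix, "_assignments.tsv"))
  utils::write.table(
    data.frame(frame = seq_along(cs$assignments),
               cluster = cs$assignments),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv)
}

#' Docking grid box centred on the receptor
#'
#' A cubic search box whose centre is the receptor's centre of gravity
#' (mass-weighted centroid of heavy atoms, standard atomic weights; set
#' `weighted = FALSE` for the geometric centroid).
#'
#' @param receptor A [structure3d].
#' @param edge Box edge in Angstrom.
#' @param spacing Grid spacing in Angstrom.
#' @param weighted Mass-weight the centroid?
#' @return A `grid_box` list: center, edge, spacing.
#' @export
grid_box <- function(receptor, edge = 40, spacing = 1, weighted = TRUE) {
  stopifnot(inherits(receptor, "structure3d"))
  if (edge <= 0 || spacing <= 0 || spacing > edge)
    stop("need edge > 0, 0 < spacing <= edge")
  heavy <- which(!(receptor$atoms$element %in% c("H", "D")))
  if (!length(heavy)) stop("receptor has no heavy atoms")
  w <- if (weighted) .atomic_weights[receptor$atoms$element[heavy]]
       else rep(1, length(heavy))
  if (anyNA(w))
    stop("no atomic weight for element(s): ",
         paste(unique(receptor$atoms$element[heavy][is.na(w)]),
               collapse = ", "))
  ctr <- colSums(receptor$xyz[heavy, , drop = FALSE] * w) / sum(w)
  structure(list(center = unname(ctr), edge = edge, spacing = spacing),
            class = "grid_box")
}

#' Render a grid box in docking config syntax
#'
#' @param box A `grid_box`.
#' @param path Optional path to write to.
#' @return Character vector of config lines (center_x/y/z, size_x/y/z),
#'   invisibly when written to file.
#' @export
write_vina_config <- function(box, path = NULL) {
  lines <- c(sprintf("center_x = %.3f", box$center[1]),
             sprintf("center_y = %.3f", box$center[2]),
             sprintf("center_z = %.3f", box$center[3]),
             sprintf("size_x = %g", box$edge),
             sprintf("size_y = %g", box$edge),
             sprintf("size_z = %g", box$edge),
             sprintf("spacing = %g", box$spacing))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
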