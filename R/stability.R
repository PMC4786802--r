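#' Ligand RMSD trace inside the binding site
#'
#' Each frame of the complex trajectory is superposed onto the reference
#' frame over the receptor fit selection; the RMSD is then measured over
#' the ligand heavy atoms without re-fitting, so drift of the ligand
#' within the site is what is measured. A ligand rigidly co-moving with
#' the receptor gives a zero trace.
#'
#' @param traj Complex [trajectory].
#' @param ligand_sel,receptor_fit_sel Disjoint selections.
#' @param ref Reference frame index.
#' @return data.frame as [rmsd_trace()].
#' @export
ligand_rmsd_trace <- function(traj, ligand_sel, receptor_fit_sel, ref = 1) {
  li <- .heavy_only(traj$topology, ligand_sel)
  ri <- .heavy_only(traj$topology, receptor_fit_sel)
  if (length(intersect(li, ri)))
    stop("selection error: ligand and receptor selections overlap")
  rmsd_trace(traj, ref = ref, fit_sel = ri, measure_sel = li)
}

#' Map a ligand trace and its binding-mode count to an RMSD score
#'
#' The qualitative three-level stability score: 3 for a very stable
#' molecule (single binding mode, mean RMSD at most `t_stable`), 2 for a
#' fluctuating molecule with a unique binding mode (single cluster, mean
#' above `t_stable`), 1 otherwise (several binding modes). The numeric
#' threshold behind "very stable" is this package's choice and is
#' configurable.
#'
#' @param trace data.frame from [ligand_rmsd_trace()].
#' @param n_clusters Number of position clusters of the ligand over the
#'   trajectory (e.g. [cluster_poses()] on trajectory snapshots).
#' @param t_stable Mean-RMSD threshold (Angstrom) for score 3.
#' @return Integer score in {1, 2, 3}.
#' @export
rmsd_score <- function(trace, n_clusters, t_stable = 1.5) {
  if (!nrow(trace)) stop("empty trace")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (n_clusters > 1) return(1L)
  if (mean(trace$values) <= t_stable) 3L else 2L
}

#' Ligand-site contact persistence
#'
#' Persistence of contacts between the ligand (treated as one residue
#' group) and each site residue, judged persistent at a 90% threshold by
#' default. Delegates to [contact_persistence()].
#'
#' @param traj Complex [trajectory].
#' @param ligand_sel,site_sel Disjoint selections.
#' @param threshold Persistence threshold (both classes set to it).
#' @param cutoff Heavy-atom contact cutoff in Angstrom.
#' @param window Frame window (default: all frames).
#' @return A `contact_table`; entries with fraction >= threshold carry
#'   class "very_persistent".
#' @export
ligand_persistence <- function(traj, ligand_sel, site_sel, threshold = 0.90,
                               cutoff = 3.0, window = NULL) {
  params <- contact_params(cutoff = cutoff, persistent = threshold,
                           very_persistent = threshold)
  contact_persistence(traj, ligand_sel, site_sel, params = params,
                      window = window)
}

#' Cluster trajectory snapshots of the ligand into binding modes
#'
#' Wraps the ligand coordinates of each frame (after receptor
#' superposition onto the reference frame) as poses and leader-clusters
#' them, giving the binding-mode count that [rmsd_score()] needs.
#'
#' @inheritParams ligand_rmsd_trace
#' @param radius Cluster radius in Angstrom.
#' @return Integer number of position clusters.
#' @export
ligand_mode_count <- function(traj, ligand_sel, receptor_fit_sel, ref = 1,
                              radius = 2.0) {
  li <- .heavy_only(traj$topology, ligand_sel)
  ri <- .heavy_only(traj$topology, receptor_fit_sel)
  refxyz <- traj$frames[[ref]]
  poses <- lapply(seq_along(traj$frames), function(f) {
    fit <- kabsch_superpose(traj$frames[[f]], refxyz, ri)
    list(compound_id = "traj", conformer_id = NA, score = f,
         element = traj$topology$atoms$element[li],
         xyz = fit$xyz[li, , drop = FALSE])
  })
  class(poses) <- "pose_set"
  attr(cluster_poses(poses, radius), "n_clusters")
}

#' Build a per-candidate stability report
#'
#' Convenience wrapper running the post-docking analytics for one
#' compound: ligand RMSD trace, binding-mode count, RMSD score and
#' persistent-contact table.
#'
#' @inheritParams ligand_rmsd_trace
#' @param compound_id Compound label.
#' @param site_sel Site selection for contact persistence.
#' @param threshold Persistence threshold.
#' @param t_stable Score-3 mean-RMSD threshold (Angstrom).
#' @param mode_radius Binding-mode cluster radius (Angstrom).
#' @return A `stability_report` list: compound_id, trace, n_modes,
#'   rmsd_score, persistent_contacts.
#' @export
stability_report <- function(traj, compound_id, ligand_sel,
                             receptor_fit_sel, site_sel = receptor_fit_sel,
                             threshold = 0.90, t_stable = 1.5,
                             mode_radius = 2.0) {
  trace <- ligand_rmsd_trace(traj, ligand_sel, receptor_fit_sel)
  nm <- ligand_mode_count(traj, ligand_sel, receptor_fit_sel,
                          radius = mode_radius)
  pc <- ligand_persistence(traj, ligand_sel, site_sel,
                           threshold = threshold)
  pc <- pc[pc$fraction >= threshold, , drop = FALSE]
  out <- list(compound_id = compound_id, trace = trace, n_modes = nm,
              rmsd_score = rmsd_score(trace, nm, t_stable = t_stable),
              persistent_contacts = pc)
  class(out) <- "stability_report"
  out
}

#' Read an externally computed binding-energy table
#'
#' TSV with columns compound_id, energy_kcal_mol and optionally method.
#' Binding energies (e.g. end-point generalized-Born estimates over the
#' final segment of each simulation) are consumed as input, never
#' computed here.
#'
#' @param path TSV path.
#' @return data.frame compound_id, energy_kcal_mol, method.
#' @export
read_energy_table <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "energy_kcal_mol") %in% names(t)))
    stop("energy table needs compound_id and energy_kcal_mol columns")
  if (is.null(t$method)) t$method <- "external"
  if (!all(is.finite(t$energy_kcal_mol))) stop("non-finite energies")
  t
}

#' Crude surrogate interaction score
#'
#' Sum over best-pose site contacts of -1.0 kcal/mol per polar and -0.5
#' per hydrophobic contact. Exists only so the pipeline can run end to
#' end when no external energy table is supplied; outputs are labelled
#' SURROGATE and are not binding free energies.
#'
#' @param n_polar,n_hydrophobic Contact counts.
#' @return Score in kcal/mol.
#' @export
surrogate_energy <- function(n_polar, n_hydrophobic) {
  -1.0 * n_polar - 0.5 * n_hydrophobic
}

#' Frame window covering the last `dt_ps` of a trajectory
#'
#' Energy-window arithmetic: the frame indices whose times lie within
#' `dt_ps` of the final frame time (e.g. the last 4 ns of a 10 ns run
#' saved every 10 ps selects the final 400 frames).
#'
#' @param traj A [trajectory] with dt metadata.
#' @param dt_ps Window length in ps.
#' @return Integer frame indices.
#' @export
last_window <- function(traj, dt_ps) {
  tt <- frame_times(traj)
  if (dt_ps <= 0) stop("window error: dt_ps must be positive")
  if (dt_ps > tt[length(tt)] - tt[1] + (if (is.na(traj$dt)) 0 else traj$dt))
    stop("window error: window longer than the trajectory")
  which(tt > tt[length(tt)] - dt_ps)
}

#' Gate and rank candidates by binding energy
#'
#' Retains the compounds passing the stability gate (at least one
#' persistent contact and RMSD score at least `min_score`) and sorts
#' them by binding energy ascending (most favourable first), producing a
#' ranked hit table: compound_id, energy_kcal_mol, method, rmsd_score,
#' persistent contact residues.
#'
#' @param reports List of `stability_report` objects.
#' @param energies data.frame from [read_energy_table()], or NULL to use
#'   the surrogate (requires `surrogate` contact counts; see details).
#' @param min_score Minimum RMSD score to retain.
#' @param surrogate Optional data.frame (compound_id, n_polar,
#'   n_hydrophobic) enabling [surrogate_energy()] for compounds missing
#'   from `energies`.
#' @return data.frame of retained compounds, ranked.
#' @export
rank_candidates <- function(reports, energies = NULL, min_score = 2L,
                            surrogate = NULL) {
  rows <- lapply(reports, function(r) {
    stopifnot(inherits(r, "stability_report"))
    keep <- nrow(r$persistent_contacts) >= 1 && r$rmsd_score >= min_score
    e <- NA_real_; method <- NA_character_
    if (!is.null(energies) && r$compound_id %in% energies$compound_id) {
      i <- match(r$compound_id, energies$compound_id)
      e <- energies$energy_kcal_mol[i]; method <- energies$method[i]
    } else if (!is.null(surrogate) &&
               r$compound_id %in% surrogate$compound_id) {
      i <- match(r$compound_id, surrogate$compound_id)
      e <- surrogate_energy(surrogate$n_polar[i],
                            surrogate$n_hydrophobic[i])
      method <- "SURROGATE"
    }
    if (keep && is.na(e))
      stop("input error: no binding energy for compound ", r$compound_id)
    data.frame(compound_id = r$compound_id, retained = keep,
               energy_kcal_mol = e, method = method,
               rmsd_score = r$rmsd_score,
               n_persistent_contacts = nrow(r$persistent_contacts),
               persistent_residues = paste(r$persistent_contacts$key_b,
                                           collapse = ","))
  })
  tab <- do.call(rbind, rows)
  out <- tab[tab$retained, , drop = FALSE]
  out <- out[order(out$energy_kcal_mol), , drop = FALSE]
  out$retained <- NULL
  rownames(out) <- NULL
  attr(out, "n_considered") <- length(reports)
  out
}
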