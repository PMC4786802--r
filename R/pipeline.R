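.schema <- list(
  simulate = list(required = character(),
                  optional = c("n_frames", "target_fractions", "k_clusters",
                               "n_compounds", "n_triage_pass", "n_gate_pass",
                               "library")),
  contacts = list(required = c("trajectory", "selA", "selB"),
                  optional = c("cutoff", "persistent", "very_persistent",
                               "window_start_ps", "dt")),
  conformers = list(required = c("trajectory"),
                    optional = c("selection", "radius", "dt")),
  filter = list(required = c("library"),
                optional = c("policy")),
  triage = list(required = c("pose_dir", "receptor", "site_sel"),
                optional = c("score_max", "pose_cluster_radius")),
  stability = list(required = c("trajectory_dir", "ligand_sel",
                                "receptor_sel"),
                   optional = c("site_sel", "energies", "threshold",
                                "t_stable", "min_score")),
  report = list(required = character(),
                optional = c("filter_json", "hits_tsv", "ranked_tsv")))

.validate_config <- function(subcommand, config) {
  sch <- .schema[[subcommand]]
  if (is.null(sch)) stop("config error: unknown subcommand ", subcommand)
  miss <- setdiff(sch$required, names(config))
  if (length(miss))
    stop("config error: missing key(s) for '", subcommand, "': ",
         paste(miss, collapse = ", "))
  unknown <- setdiff(names(config), c(sch$required, sch$optional))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  for (k in intersect(c("trajectory", "library", "receptor", "energies"),
                      names(config)))
    if (!file.exists(config[[k]]))
      stop("config error: input file not found: ", config[[k]])
  invisible(TRUE)
}

.write_manifest <- function(out_dir, subcommand, config, seed) {
  jsonlite::write_json(
    list(tool = "rcscreen",
         version = as.character(utils::packageVersion("rcscreen")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         subcommand = subcommand,
         seed = seed,
         config_hash = .config_hash(config),
         config = config),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- if (length(config)) config[order(names(config))] else list()
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run one stage of the screening pipeline
#'
#' Subcommands: `simulate` (write planted synthetic inputs), `contacts`
#' (persistence table + residue profile), `conformers` (receptor
#' conformer extraction), `filter` (library filter cascade), `triage`
#' (docking-pose hit selection), `stability` (per-candidate stability
#' reports + ranked table) and `report` (merge stage outputs). The
#' config is validated against the stage schema before any computation;
#' a run manifest (package version, config hash, seed) is always written
#' once validation passes. Given one config and seed, outputs are
#' byte-identical across runs.
#'
#' @param subcommand Stage name, see above.
#' @param config Named list, or path to a YAML/JSON config file.
#' @param out_dir Output directory (created).
#' @param seed RNG seed used for every stochastic stage.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(subcommand, config = list(), out_dir = ".",
                         seed = 1) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::fromJSON(config) else yaml::read_yaml(config)
    config <- as.list(config)
  }
  .validate_config(subcommand, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_manifest(out_dir, subcommand, config, seed)
  g <- function(key, default) config[[key]] %||% default
  arts <- list(manifest = file.path(out_dir, "manifest.json"))
  if (subcommand == "simulate") {
    ct <- make_contact_trajectory(
      g("target_fractions", c(0.95, 0.85, 0.5)),
      n_frames = g("n_frames", 100), seed = seed,
      dir = file.path(out_dir, "contacts"))
    en <- make_conformer_ensemble(
      k = g("k_clusters", 3), seed = seed + 1,
      dir = file.path(out_dir, "ensemble"))
    cs <- campaign_spec(g("n_compounds", 29), g("n_triage_pass", 29),
                        g("n_gate_pass", 11), seed = seed + 2)
    make_pose_campaign(cs, seed = seed + 3,
                       dir = file.path(out_dir, "campaign"))
    make_library(n_compliant = 5, violators = c("mw<450", "tpsa<110"),
                 n_duplicates = 1, n_pains = 1, n_reactive = 1,
                 seed = seed + 4,
                 path = file.path(out_dir, "library.smi"))
    arts$dirs <- file.path(out_dir, c("contacts", "ensemble", "campaign"))
    arts$library <- file.path(out_dir, "library.smi")
  } else if (subcommand == "contacts") {
    traj <- read_multimodel_pdb(config$trajectory, dt = g("dt", NA_real_))
    if (!is.null(config$window_start_ps))
      traj <- analysis_window(traj, config$window_start_ps)
    params <- contact_params(g("cutoff", 3.0), g("persistent", 0.80),
                             g("very_persistent", 0.90))
    tab <- contact_persistence(traj, config$selA, config$selB, params)
    arts$contacts <- write_contact_table(
      tab, file.path(out_dir, "contact_persistence.tsv"))
    if (nrow(tab)) {
      prof <- residue_profile(tab, params = params)
      utils::write.table(prof, file.path(out_dir, "residue_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      arts$profile <- file.path(out_dir, "residue_profile.tsv")
    }
  } else if (subcommand == "conformers") {
    traj <- read_multimodel_pdb(config$trajectory, dt = g("dt", NA_real_))
    cs <- cluster_conformers(traj, g("selection", "mainchain"),
                             g("radius", 2.0))
    arts$assignments <- export_conformers(cs, traj,
                                          file.path(out_dir, "conformers"))
  } else if (subcommand == "filter") {
    lib <- parse_library(config$library)
    dd <- dedup_library(lib)
    audit <- apply_filters(dd$unique)
    arts$audit <- write_filter_audit(
      audit, file.path(out_dir, "filter_audit.tsv"),
      json = file.path(out_dir, "filter_summary.json"),
      pass_smi = file.path(out_dir, "pass.smi"), lib = dd$unique)
    utils::write.table(dd$duplicates,
                       file.path(out_dir, "duplicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (subcommand == "triage") {
    files <- list.files(config$pose_dir, pattern = "\\.pdbqt$",
                        full.names = TRUE)
    if (!length(files)) stop("no PDBQT files in ", config$pose_dir)
    posesets <- lapply(files, read_vina_poses)
    receptor <- read_pdb_structure(config$receptor)
    crit <- triage_criteria(
      score_max = g("score_max", -7.0),
      pose_cluster_radius = g("pose_cluster_radius", 2.0))
    hits <- select_hits(posesets, receptor, config$site_sel, crit)
    arts$hits <- write_hit_table(hits, file.path(out_dir, "hits.tsv"))
  } else if (subcommand == "stability") {
    files <- list.files(config$trajectory_dir, pattern = "\\.pdb$",
                        full.names = TRUE)
    if (!length(files)) stop("no trajectories in ", config$trajectory_dir)
    energies <- if (!is.null(config$energies))
      read_energy_table(config$energies)
    reports <- lapply(files, function(f)
      stability_report(read_multimodel_pdb(f, dt = 10),
                       compound_id = sub("\\.pdb$", "", basename(f)),
                       ligand_sel = config$ligand_sel,
                       receptor_fit_sel = config$receptor_sel,
                       site_sel = g("site_sel", config$receptor_sel),
                       threshold = g("threshold", 0.90),
                       t_stable = g("t_stable", 1.5)))
    ranked <- rank_candidates(reports, energies,
                              min_score = g("min_score", 2L))
    utils::write.table(ranked, file.path(out_dir, "ranked.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    arts$ranked <- file.path(out_dir, "ranked.tsv")
  } else if (subcommand == "report") {
    rep <- list()
    if (!is.null(config$filter_json) && file.exists(config$filter_json))
      rep$filter <- jsonlite::fromJSON(config$filter_json)
    if (!is.null(config$hits_tsv) && file.exists(config$hits_tsv)) {
      h <- utils::read.delim(config$hits_tsv)
      rep$triage <- list(n_compounds = nrow(h), n_pass = sum(h$verdict))
    }
    if (!is.null(config$ranked_tsv) && file.exists(config$ranked_tsv)) {
      r <- utils::read.delim(config$ranked_tsv)
      rep$stability <- list(n_retained = nrow(r),
                            best = if (nrow(r)) r$compound_id[1] else NA)
    }
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    arts$report <- file.path(out_dir, "report.json")
  }
  invisible(arts)
}
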