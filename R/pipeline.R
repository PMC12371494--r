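#' Default run configuration
#'
#' Hierarchical configuration for [run_pipeline()].  Every stage
#' parameter defaults to the analysis' standard value: bound-frame cutoff
#' 5 Angstrom, subsampling window 100-200 ns at 1 ns, k = 2 mixture
#' components, 60% residual-signal triage cutoff, 3 nM probe with Kd
#' 5/7/5 nM (DF2/DC2/DC1).
#'
#' @param seed root seed; all stage randomness derives from it.
#' @param out_dir output directory for artifacts.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = "posepop_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      n_replicates = 8L, n_frames_per_replicate = 200L, frame_interval = 1,
      pose_weight_A = 0.55, positional_noise_sd = 0.3,
      unbound_fraction = 0.1, unbound_offset = 3,
      assay = list(true_ic50 = 1e-5, hill_slope = 1, top = 100, bottom = 0,
                   noise_cv = 0.02, n_replicates = 4L,
                   compound = "CPD1", protein = "DF2", assay = "FP"),
      docking = list(n_poses = 20L, planted_binders = 3L)
    ),
    cluster = list(t_start = 100, t_end = 200, interval = 1,
                   threshold = 5.0, k = 2L),
    assay = list(residual_cutoff = 60,
                 probe = list(probe_concentration = 3e-9,
                              probe_kd = list(DF2 = 5e-9, DC2 = 7e-9,
                                              DC1 = 5e-9))),
    triage = list(top_n = 10L,
                  hbond = list(max_donor_acceptor_distance = 3.5,
                               min_angle_at_hydrogen = 120,
                               heavy_atom_fallback_distance = 3.5))
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param file path to a YAML (or JSON) configuration file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  user <- yaml::read_yaml(file)
  config <- modify_list_deep(default_run_config(), user)
  validate_run_config(config)
  config
}

modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a run configuration
#'
#' @param config a `run_config`.
#' @return `config`, invisibly; invalid fields raise an error naming the
#'   offending field.
#' @export
validate_run_config <- function(config) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid config field '", field, "': ", msg)
  }
  chk(is.numeric(config$seed) && length(config$seed) == 1L, "seed",
      "must be a single integer")
  sim <- config$simulate
  chk(sim$n_replicates >= 1, "simulate.n_replicates", "must be >= 1")
  chk(sim$n_frames_per_replicate >= 1, "simulate.n_frames_per_replicate",
      "must be >= 1")
  chk(sim$pose_weight_A >= 0 && sim$pose_weight_A <= 1,
      "simulate.pose_weight_A", "must lie in [0, 1]")
  chk(sim$unbound_fraction >= 0 && sim$unbound_fraction < 1,
      "simulate.unbound_fraction", "must lie in [0, 1)")
  cl <- config$cluster
  chk(cl$t_start < cl$t_end, "cluster.t_start", "must be < cluster.t_end")
  chk(cl$threshold > 0, "cluster.threshold", "must be positive")
  chk(cl$k >= 1, "cluster.k", "must be >= 1")
  chk(config$assay$residual_cutoff > 0, "assay.residual_cutoff",
      "must be positive")
  chk(config$triage$top_n >= 1, "triage.top_n", "must be >= 1")
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> cluster-poses -> fit-assay -> triage on one root
#' seed, writing every artifact plus a manifest (inputs, parameters,
#' seed, package version, per-stage counts) under `config$out_dir`.
#' Stages never mutate their inputs; re-running with the same
#' configuration reproduces the outputs.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param stages character subset of
#'   `c("simulate", "cluster", "assay", "triage")` (default: all; later
#'   stages read the artifacts of earlier ones, so `"simulate"` must have
#'   run at least once into the same directory).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "cluster", "assay", "triage")) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("posepop")),
                   parameters = config[setdiff(names(config), "out_dir")],
                   stages = list())
  topology <- make_pocket_topology()

  if ("simulate" %in% stages) {
    sim <- config$simulate
    tspec <- trajectory_gen_spec(
      n_replicates = sim$n_replicates,
      n_frames_per_replicate = sim$n_frames_per_replicate,
      frame_interval = sim$frame_interval,
      pose_weight_A = sim$pose_weight_A,
      positional_noise_sd = sim$positional_noise_sd,
      unbound_fraction = sim$unbound_fraction,
      unbound_offset = sim$unbound_offset,
      seed = config$seed)
    trajs <- generate_trajectory(tspec, topology)
    for (tr in trajs) {
      write_trajectory_pdb(tr, path(paste0("traj_", tr$replicate_id, ".pdb")))
    }
    write_ground_truth(trajs, path("traj_ground_truth.json"))
    aspec <- do.call(assay_gen_spec, c(sim$assay, list(seed = config$seed + 1L)))
    panel <- generate_dose_response(aspec)
    utils::write.csv(panel, path("assay_panel.csv"), row.names = FALSE)
    dock <- generate_docking_poses(sim$docking$n_poses, topology,
                                   planted_binders = sim$docking$planted_binders,
                                   seed = config$seed + 2L)
    write_docking_poses(dock, path("docking_poses.pdb"), path("docking_scores.csv"))
    write_ground_truth(dock, path("docking_ground_truth.json"))
    manifest$stages$simulate <- list(
      n_trajectory_frames = sim$n_replicates * sim$n_frames_per_replicate,
      n_assay_records = nrow(panel), n_docking_poses = sim$docking$n_poses)
  }

  if ("cluster" %in% stages) {
    sim <- config$simulate
    tspec <- trajectory_gen_spec(
      n_replicates = sim$n_replicates,
      n_frames_per_replicate = sim$n_frames_per_replicate,
      frame_interval = sim$frame_interval,
      pose_weight_A = sim$pose_weight_A,
      positional_noise_sd = sim$positional_noise_sd,
      unbound_fraction = sim$unbound_fraction,
      unbound_offset = sim$unbound_offset,
      seed = config$seed)
    trajs <- generate_trajectory(tspec, topology)
    cl <- config$cluster
    fit <- cluster_poses(trajs, t_start = cl$t_start, t_end = cl$t_end,
                         interval = cl$interval, threshold = cl$threshold,
                         k = cl$k, seed = config$seed)
    write_cluster_report(fit, path("cluster_report.json"),
                         path("cluster_assignments.csv"))
    sub <- lapply(trajs, subsample, t_start = cl$t_start, t_end = cl$t_end,
                  interval = cl$interval)
    sub <- structure(sub, class = "trajectory_set")
    ref <- reference_frame(sub[[1L]], 1L)
    series <- ligand_rmsd(sub, ref)
    write_rmsd_series(series, path("rmsd_series.csv"))
    manifest$stages$cluster <- c(as.list(fit$counts),
                                 list(populations = as.list(fit$populations)))
  }

  if ("assay" %in% stages) {
    panel_file <- path("assay_panel.csv")
    if (!file.exists(panel_file)) {
      stop("missing input: ", panel_file, " (run the simulate stage first)")
    }
    panel <- read_assay_panel(panel_file)
    probe <- probe_spec(config$assay$probe$probe_concentration,
                        unlist(config$assay$probe$probe_kd))
    affinity <- fit_affinity_panel(panel, probe = probe)
    utils::write.csv(affinity, path("affinity_table.csv"), row.names = FALSE)
    summary <- screen_summary(data.frame(compound = affinity$compound,
                                         active = affinity$status == "ok"))
    jsonlite::write_json(summary, path("screen_summary.json"),
                         auto_unbox = TRUE, digits = 10)
    manifest$stages$assay <- list(n_compounds_fitted = nrow(affinity),
                                  n_determined = sum(affinity$status == "ok"))
  }

  if ("triage" %in% stages) {
    poses_file <- path("docking_poses.pdb")
    scores_file <- path("docking_scores.csv")
    for (f in c(poses_file, scores_file)) {
      if (!file.exists(f)) {
        stop("missing input: ", f, " (run the simulate stage first)")
      }
    }
    scores <- utils::read.csv(scores_file, stringsAsFactors = FALSE)
    ptraj <- read_trajectory_pdb(poses_file)
    poses <- lapply(seq_len(n_frames(ptraj)), function(i) {
      co <- frame_coords(ptraj, i)
      at <- ptraj$atoms
      at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
      dock_pose(scores$pose_id[i], at, e_total = scores$E_total[i],
                delec = scores$Delec[i])
    })
    crit <- do.call(hbond_criteria, config$triage$hbond)
    report <- triage_report(poses, topology, crit, top_n = config$triage$top_n)
    utils::write.csv(report$table, path("triage_table.csv"), row.names = FALSE)
    jsonlite::write_json(report$fingerprints, path("triage_fingerprints.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = 10)
    manifest$stages$triage <- list(n_poses = length(poses),
                                   n_selected = length(report$selected))
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = 10)
  invisible(manifest)
}
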