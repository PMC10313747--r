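# Stage orchestration: each analysis stage reads the configured inputs,
# runs the corresponding module, and writes a CSV named after the stage.
# `run_all()` composes every stage; a manifest (config echo + versions +
# seed) is always written.

PIPELINE_STAGES <- c("simulate", "rmsd", "rmsf", "sasa", "contacts",
                     "hbonds", "map", "sie", "decompose", "fel")

log_stage <- function(fmt, ...) {
  message(sprintf("[sietraj] %s", sprintf(fmt, ...)))
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

load_inputs <- function(cfg) {
  if (is.null(cfg$structure))
    stop_data("no 'structure' input configured")
  s <- read_pdb(cfg$structure, ligand_resnames = cfg$ligand_resnames)
  if (inherits(s, "trajectory")) {
    top <- s$topology; ref <- frame_coords(s, 1); traj <- s
  } else {
    top <- s$topology; ref <- s$coords; traj <- NULL
  }
  if (!is.null(cfg$parameters))
    top <- read_parameter_table(cfg$parameters, top)
  if (!is.null(cfg$trajectory)) {
    traj <- if (grepl("\\.xyz$", cfg$trajectory, ignore.case = TRUE))
      read_xyz(cfg$trajectory, top)
    else {
      t2 <- read_pdb(cfg$trajectory, ligand_resnames = cfg$ligand_resnames)
      if (!inherits(t2, "trajectory"))
        stop_data("'%s' holds a single model, not a trajectory",
                  cfg$trajectory)
      trajectory(top, t2$coords, t2$times)
    }
  } else if (!is.null(traj)) {
    traj <- trajectory(top, traj$coords, traj$times)
  }
  if (is.null(traj)) stop_data("no trajectory input configured")
  list(topology = top, reference = ref, traj = traj)
}

cfg_window <- function(cfg, traj) {
  w <- cfg$window
  if (!is.null(w$start) || !is.null(w$end)) {
    s <- w$start %||% 1L; e <- w$end %||% n_frames(traj)
    if (s < 1L || e > n_frames(traj) || s > e)
      stop_data("window [%s, %s] outside trajectory of %d frames",
                s, e, n_frames(traj))
    return(seq.int(s, e))
  }
  tail_window(traj, w$fraction %||% 0.1)
}

stage_simulate <- function(cfg) {
  sim <- cfg$simulate %||% list()
  cx <- make_toy_complex(
    n_residues = sim$n_residues %||% 50L,
    seed = cfg$seed,
    contact_atoms = sim$contact_atoms %||%
      ((sim$contact_count_target %||% 18L) - 1L),
    gate_distance = sim$gate_distance %||% 22.0)
  gp <- gate_params(
    n_frames = sim$n_frames %||% 2000L,
    basin_means = unlist(sim$basin_means) %||% c(19.0, 22.0),
    basin_sigmas = unlist(sim$basin_sigmas) %||% c(0.4, 0.4),
    switch_prob = sim$switch_prob %||% 0.05,
    occupancy_target = sim$occupancy_target %||% 0.5,
    jitter_sigma = sim$jitter_sigma %||% 0.15,
    loop_jitter_sigma = sim$loop_jitter_sigma,
    seed = cfg$seed)
  traj <- simulate_gate_trajectory(cx, gp)
  lp <- ligand_script_params(
    occupancies = unlist(sim$hbond_occupancies) %||% c(0.7, 0.4),
    contact_count_target = sim$contact_count_target %||% 18L,
    seed = cfg$seed + 1L)
  traj <- script_ligand_interactions(traj, lp)
  meta <- attr(cx$topology, "toy_meta")
  out_dir <- cfg$out_dir
  write_pdb(cx, file.path(out_dir, "complex.pdb"))
  write_parameter_table(cx$topology, file.path(out_dir, "parameters.tsv"))
  write_xyz(traj, file.path(out_dir, "trajectory.xyz"))
  log_stage("simulate: %d frames, loops %s / %s", n_frames(traj),
            meta$loopA_range, meta$loopB_range)
  list(complex = cx, traj = traj, meta = meta)
}

loop_selections <- function(cfg, top) {
  sel <- cfg$selections %||% list()
  meta <- attr(top, "toy_meta")
  la <- sel$loop_a %||% meta$loopA_range
  lb <- sel$loop_b %||% meta$loopB_range
  if (is.null(la) || is.null(lb))
    stop_config("selections.loop_a and selections.loop_b are required")
  list(a = selection(la, atoms = "CA"), b = selection(lb, atoms = "CA"))
}

#' Run one pipeline stage
#'
#' @param cfg a [run_config()].
#' @param stage one of `"simulate"`, `"rmsd"`, `"rmsf"`, `"sasa"`,
#'   `"contacts"`, `"hbonds"`, `"map"`, `"sie"`, `"decompose"`, `"fel"`.
#' @param inputs optional preloaded inputs (as returned by the internal
#'   loader); used by [run_all()] to avoid re-reading files.
#' @return invisibly, a list of written file paths.
#' @export
run_stage <- function(cfg, stage, inputs = NULL) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()["elapsed"]
  if (stage == "simulate") {
    stage_simulate(cfg)
    paths <- file.path(cfg$out_dir,
                       c("complex.pdb", "parameters.tsv", "trajectory.xyz"))
    log_stage("simulate done in %.1f s", proc.time()["elapsed"] - t0)
    return(invisible(paths))
  }
  inp <- inputs %||% load_inputs(cfg)
  traj <- inp$traj
  fit_sel <- selection(cfg$selections$fit %||% "all", atoms = "CA")
  window <- cfg_window(cfg, traj)
  paths <- character()
  if (stage == "rmsd") {
    df <- rmsd_series(traj, reference = inp$reference, fit_sel = fit_sel)
    paths <- write_stage_csv(df, cfg$out_dir, "rmsd")
  } else if (stage == "rmsf") {
    df <- rmsf_per_residue(traj, fit_sel = fit_sel)
    paths <- write_stage_csv(df, cfg$out_dir, "rmsf")
  } else if (stage == "sasa") {
    df <- binding_site_sasa_series(traj, cfg_sasa(cfg), frames = window)
    paths <- write_stage_csv(df, cfg$out_dir, "sasa")
  } else if (stage %in% c("contacts", "hbonds")) {
    df <- interaction_series(traj, cfg_contact(cfg), cfg_hbond(cfg),
                             frames = window)
    paths <- write_stage_csv(df[, c("frame", "time_ps", "n_contacts")],
                             cfg$out_dir, "contacts")
    paths <- c(paths,
               write_stage_csv(df[, c("frame", "time_ps", "n_hbonds")],
                               cfg$out_dir, "hbonds"))
  } else if (stage == "map") {
    df <- interaction_map(traj, cfg_contact(cfg), cfg_hbond(cfg),
                          window = window)
    paths <- write_stage_csv(df, cfg$out_dir, "interaction_map")
  } else if (stage == "sie") {
    sie_cfg <- cfg$criteria$sie
    res <- sie_from_trajectory(traj, cfg_sie(cfg), window = window,
                               n_snapshots = min(sie_cfg$n_snapshots,
                                                 length(window)),
                               sasa = cfg_sasa(cfg),
                               eps_in = sie_cfg$eps_in,
                               eps_out = sie_cfg$eps_out)
    paths <- write_stage_csv(res$per_snapshot, cfg$out_dir, "sie")
    paths <- c(paths, write_stage_csv(
      data.frame(mean_dg_bind = res$mean, sd_dg_bind = res$sd,
                 n_snapshots = nrow(res$per_snapshot)),
      cfg$out_dir, "sie_summary"))
  } else if (stage == "decompose") {
    sie_cfg <- cfg$criteria$sie
    df <- per_residue_decomposition(
      traj, window = window,
      n_snapshots = min(sie_cfg$n_snapshots, length(window)),
      gamma = sie_cfg$gamma, sasa = cfg_sasa(cfg),
      eps_in = sie_cfg$eps_in, eps_out = sie_cfg$eps_out,
      key_threshold = cfg$criteria$thresholds$key_residue)
    paths <- write_stage_csv(
      df[, c("resno", "resname", "vdw_term", "ele_term", "total", "is_key")],
      cfg$out_dir, "decomposition")
  } else if (stage == "fel") {
    loops <- loop_selections(cfg, traj$topology)
    res <- fel_pipeline(traj, loops$a, loops$b, cfg_fel(cfg),
                        cfg_thresholds(cfg), fit_sel = fit_sel,
                        min_separation_bins =
                          cfg$criteria$fel$min_separation_bins)
    paths <- write_stage_csv(fel_grid_table(res$grid), cfg$out_dir,
                             "fel_grid")
    paths <- c(paths, write_stage_csv(res$basins, cfg$out_dir, "fel_basins"))
    paths <- c(paths, write_stage_csv(
      data.frame(frame = seq_along(res$labels),
                 distance_A = res$x, loop_rmsd_A = res$y,
                 conformation = res$labels),
      cfg$out_dir, "fel_labels"))
  }
  log_stage("%s done in %.1f s", stage, proc.time()["elapsed"] - t0)
  invisible(paths)
}

write_manifest <- function(cfg) {
  manifest <- list(
    package = "sietraj",
    version = as.character(utils::packageVersion("sietraj")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg))
  path <- file.path(cfg$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}

#' Run the full pipeline
#'
#' Runs `simulate` when the configuration has no structure input but a
#' `simulate` block, then every analysis stage, and writes the run
#' manifest.
#'
#' @param cfg a [run_config()].
#' @return invisibly, all written file paths.
#' @export
run_all <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (is.null(cfg$structure)) {
    sim <- stage_simulate(cfg)
    paths <- file.path(cfg$out_dir,
                       c("complex.pdb", "parameters.tsv", "trajectory.xyz"))
    cfg$structure <- file.path(cfg$out_dir, "complex.pdb")
    cfg$parameters <- file.path(cfg$out_dir, "parameters.tsv")
    cfg$trajectory <- file.path(cfg$out_dir, "trajectory.xyz")
    if (is.null(cfg$selections$loop_a)) {
      cfg$selections$loop_a <- sim$meta$loopA_range
      cfg$selections$loop_b <- sim$meta$loopB_range
    }
  }
  inputs <- load_inputs(cfg)
  for (stage in setdiff(PIPELINE_STAGES, c("simulate", "hbonds")))
    paths <- c(paths, run_stage(cfg, stage, inputs = inputs))
  paths <- c(paths, write_manifest(cfg))
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommand interface over the pipeline:
#' `sietraj <stage|all> --config run.yaml [--seed N] [--out-dir DIR]
#' [--frames A-B]`.  Exit code 0 on success, 2 on configuration errors
#' (message names the offending key), 1 on data errors.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: sietraj <",
                  paste(c(PIPELINE_STAGES, "all"), collapse = "|"),
                  "> [--config FILE] [--seed N] [--out-dir DIR] ",
                  "[--frames A-B]")
  if (!length(argv) || argv[1] %in% c("-h", "--help")) {
    message(usage)
    return(0L)
  }
  stage <- argv[1]
  if (!stage %in% c(PIPELINE_STAGES, "all")) {
    message("unknown subcommand '", stage, "'\n", usage)
    return(2L)
  }
  opts <- list(); i <- 2L
  while (i <= length(argv)) {
    key <- argv[i]
    if (!grepl("^--", key) || i == length(argv)) {
      message("malformed argument '", key, "'\n", usage)
      return(2L)
    }
    opts[[sub("^--", "", key)]] <- argv[i + 1L]
    i <- i + 2L
  }
  tryCatch({
    overrides <- list()
    if (!is.null(opts$seed)) overrides$seed <- as.integer(opts$seed)
    if (!is.null(opts[["out-dir"]])) overrides$out_dir <- opts[["out-dir"]]
    cfg <- run_config(opts$config %||% list(), overrides = overrides)
    if (!is.null(opts$frames)) {
      ab <- as.integer(strsplit(opts$frames, "-")[[1]])
      if (length(ab) != 2L || anyNA(ab))
        stop_config("--frames must look like A-B")
      cfg$window <- list(start = ab[1], end = ab[2])
    }
    if (stage == "all") run_all(cfg) else {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      run_stage(cfg, stage)
      write_manifest(cfg)
    }
    0L
  }, sietraj_config_error = function(e) {
    message("configuration error: ", conditionMessage(e))
    2L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
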