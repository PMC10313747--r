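# Run configuration: a YAML file validated against a fixed schema before
# any computation.  Numeric defaults are the analysis constants used
# throughout the package (3.50 A contacts, 150.00 degree H-bond angle,
# 5.00 A SASA shell, 0.10 A FEL bins at 310.00 K, 100 SIE snapshots,
# -1.00 kcal/mol key-residue threshold, SIE coefficients 0.105 / 0.013 /
# -2.89).

config_schema <- function() {
  list(
    version = NULL, structure = NULL, trajectory = NULL, parameters = NULL,
    ligand_resnames = NULL, out_dir = NULL, seed = NULL,
    selections = list(loop_a = NULL, loop_b = NULL, fit = NULL),
    criteria = list(
      contact = list(cutoff = NULL, heavy_atoms_only = NULL),
      hbond = list(max_da_distance = NULL, min_dha_angle = NULL),
      sasa = list(probe_radius = NULL, n_sphere_points = NULL,
                  shell_cutoff = NULL),
      sie = list(alpha = NULL, gamma = NULL, constant = NULL,
                 n_snapshots = NULL, eps_in = NULL, eps_out = NULL),
      fel = list(bin_width = NULL, temperature = NULL,
                 min_separation_bins = NULL),
      thresholds = list(d_open = NULL, d_close = NULL, boundary = NULL,
                        key_residue = NULL)),
    window = list(fraction = NULL, start = NULL, end = NULL),
    simulate = list(n_residues = NULL, n_frames = NULL, occupancy_target = NULL,
                    switch_prob = NULL, basin_means = NULL,
                    basin_sigmas = NULL, jitter_sigma = NULL,
                    loop_jitter_sigma = NULL, hbond_occupancies = NULL,
                    contact_count_target = NULL, contact_atoms = NULL,
                    gate_distance = NULL))
}

validate_keys <- function(cfg, schema, path = "") {
  for (k in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(schema))
      stop_config("unknown configuration key '%s'", full)
    if (is.list(schema[[k]]) && !is.null(cfg[[k]])) {
      if (!is.list(cfg[[k]]))
        stop_config("configuration key '%s' must be a mapping", full)
      validate_keys(cfg[[k]], schema[[k]], full)
    }
  }
  invisible(TRUE)
}

config_defaults <- function() {
  list(version = 1,
       ligand_resnames = "LIG",
       out_dir = "sietraj_out",
       seed = 1L,
       selections = list(fit = "all"),
       criteria = list(
         contact = list(cutoff = 3.5, heavy_atoms_only = TRUE),
         hbond = list(max_da_distance = 3.5, min_dha_angle = 150.0),
         sasa = list(probe_radius = 1.4, n_sphere_points = 960L,
                     shell_cutoff = 5.0),
         sie = list(alpha = 0.105, gamma = 0.013, constant = -2.89,
                    n_snapshots = 100L, eps_in = 2.25, eps_out = 78.5),
         fel = list(bin_width = 0.10, temperature = 310.0,
                    min_separation_bins = 10L),
         thresholds = list(d_open = 22.0, d_close = 19.0,
                           key_residue = -1.0)),
       window = list(fraction = 0.1))
}

merge_defaults <- function(cfg, defaults) {
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(cfg[[k]])) {
      cfg[[k]] <- merge_defaults(cfg[[k]], defaults[[k]])
    }
  }
  cfg
}

#' Load and validate a run configuration
#'
#' @param x path to a YAML configuration file, or a named list.
#' @param overrides named list merged over the file's values (CLI flags).
#' @return validated configuration list of class `run_config`, with
#'   defaults filled in.
#' @export
run_config <- function(x = list(), overrides = list()) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop_config("configuration file not found: '%s'", x)
    yaml::read_yaml(x) %||% list()
  } else if (is.list(x)) x else
    stop_config("configuration must be a file path or a list")
  for (k in names(overrides))
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  validate_keys(cfg, config_schema())
  cfg <- merge_defaults(cfg, config_defaults())
  if (!is.null(cfg$window$fraction) &&
      (cfg$window$fraction <= 0 || cfg$window$fraction > 1))
    stop_config("window.fraction must be in (0, 1]")
  structure(cfg, class = c("run_config", "list"))
}

# Criteria objects from a validated config.
cfg_contact <- function(cfg) with(cfg$criteria$contact,
  contact_criteria(cutoff, heavy_atoms_only))
cfg_hbond <- function(cfg) with(cfg$criteria$hbond,
  hbond_criteria(max_da_distance, min_dha_angle))
cfg_sasa <- function(cfg) with(cfg$criteria$sasa,
  sasa_params(probe_radius, n_sphere_points, shell_cutoff))
cfg_sie <- function(cfg) with(cfg$criteria$sie,
  sie_coefficients(alpha, gamma, constant))
cfg_fel <- function(cfg) with(cfg$criteria$fel,
  fel_params(bin_width, bin_width, temperature))
cfg_thresholds <- function(cfg) {
  th <- cfg$criteria$thresholds
  if (is.null(th$boundary))
    conformation_thresholds(th$d_open, th$d_close)
  else conformation_thresholds(th$d_open, th$d_close, th$boundary)
}
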