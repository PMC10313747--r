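# Solvent-accessible surface area (Shrake-Rupley) and the ligand-proximal
# shell series.

#' SASA parameters
#'
#' @param probe_radius solvent probe radius in Angstrom (1.4 = water).
#' @param n_sphere_points quadrature points per atom (Fibonacci lattice);
#'   at least 92.
#' @param shell_cutoff Angstrom cutoff defining the ligand-proximal residue
#'   shell for [binding_site_sasa_series()].
#' @return an object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960L,
                        shell_cutoff = 5.0) {
  check_numeric_scalar(probe_radius, "probe_radius", positive = TRUE)
  if (n_sphere_points < 92L)
    stop_config("'n_sphere_points' must be >= 92")
  check_numeric_scalar(shell_cutoff, "shell_cutoff", positive = TRUE)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 shell_cutoff = shell_cutoff),
            class = "sasa_params")
}

#' Shrake-Rupley per-atom SASA
#'
#' Each atom's van der Waals sphere is inflated by the probe radius and
#' covered with a deterministic quasi-uniform point lattice; the accessible
#' fraction is the share of points not buried inside any neighbour's
#' inflated sphere.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii; defaults to the topology's
#'   `vdw_radius` column when `top` is given.
#' @param params a [sasa_params()].
#' @param top optional [topology()] supplying radii.
#' @param subset optional integer indices: only these atoms' areas are
#'   computed (all atoms still occlude).
#' @return numeric vector of per-atom areas in Angstrom^2 (zero for atoms
#'   outside `subset`).
#' @export
shrake_rupley_sasa <- function(coords, radii = NULL, params = sasa_params(),
                               top = NULL, subset = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(radii)) {
    if (is.null(top)) stop_data("need 'radii' or a parameterised 'top'")
    radii <- top$atoms$vdw_radius
  }
  if (length(radii) != n)
    stop_data("radii length %d does not match %d atoms", length(radii), n)
  bad <- which(!is.finite(radii) | radii <= 0)
  if (length(bad))
    stop_data("missing/invalid vdw radius for atom(s) %s",
              paste(utils::head(bad, 10), collapse = ", "))
  pr <- params$probe_radius
  rexp <- radii + pr
  pts <- sphere_points(params$n_sphere_points)
  if (is.null(subset)) subset <- seq_len(n)
  # neighbour search via cell-free cutoff on pair distances
  dmat <- cross_dist(coords, coords)
  area <- numeric(n)
  for (i in subset) {
    nb <- which(dmat[i, ] < rexp[i] + rexp & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * rexp[i]^2
      next
    }
    p <- sweep(pts * rexp[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb[order(dmat[i, nb])]) {
      if (!any(acc)) break
      acc[acc] <- dist2_point(coords[j, ], p[acc, , drop = FALSE]) >= rexp[j]^2
    }
    area[i] <- mean(acc) * 4 * pi * rexp[i]^2
  }
  area
}

# Receptor residues with any atom within `cutoff` of any ligand atom.
shell_residues <- function(coords, top, cutoff) {
  rec <- top$groups$receptor; lig <- top$groups$ligand
  if (!length(lig)) stop_data("empty ligand group")
  d <- cross_dist(coords[rec, , drop = FALSE], coords[lig, , drop = FALSE])
  near <- rec[apply(d, 1, min) <= cutoff]
  sort(unique(top$atoms$resno[near]))
}

#' Binding-site SASA series
#'
#' Per frame, the receptor residues with any atom within `shell_cutoff` of
#' any ligand atom are identified (whole-residue granularity, recomputed
#' every frame), and their solvent-accessible area computed in the full
#' complex is summed.  This tracks how much of the binding-site surface
#' stays water-exposed while the ligand is bound.
#'
#' @param traj a [trajectory()] with receptor/ligand groups and vdw radii.
#' @param params a [sasa_params()].
#' @param frames optional integer frame indices (default: all frames).
#' @return data frame with `frame`, `time_ps`, `shell_residue_count`,
#'   `shell_sasa_A2`.
#' @export
binding_site_sasa_series <- function(traj, params = sasa_params(),
                                     frames = NULL) {
  top <- traj$topology
  if (!length(top$groups$ligand)) stop_data("empty ligand group")
  frames <- frames %||% seq_len(n_frames(traj))
  resno <- top$atoms$resno
  warned <- FALSE
  out <- lapply(frames, function(f) {
    m <- frame_coords(traj, f)
    shell <- shell_residues(m, top, params$shell_cutoff)
    if (!length(shell)) {
      if (!warned) {
        warning("no receptor residues within the ligand shell in frame ", f)
        warned <<- TRUE
      }
      return(c(0, 0))
    }
    idx <- which(resno %in% shell & seq_len(n_atoms(top)) %in% top$groups$receptor)
    a <- shrake_rupley_sasa(m, params = params, top = top, subset = idx)
    c(length(shell), sum(a[idx]))
  })
  out <- do.call(rbind, out)
  data.frame(frame = frames, time_ps = traj$times[frames],
             shell_residue_count = as.integer(out[, 1]),
             shell_sasa_A2 = out[, 2])
}
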