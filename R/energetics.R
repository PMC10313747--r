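# Intermolecular energy terms, the solvated interaction energy (SIE)
# combination, and per-residue decomposition with the key-residue filter.
#
# SIE is an end-point estimate of the binding free energy:
#
#   dG_bind = alpha * (E_vdw + gamma*dSA + E_ele + G_RF) + C
#
# where E_vdw and E_ele are the intermolecular Lennard-Jones and Coulomb
# energies of the bound complex, gamma*dSA is the cavity (nonpolar
# solvation) term driven by buried surface area, and G_RF is the change in
# electrostatic reaction-field (polar solvation) energy upon binding.  The
# calibrated coefficients alpha = 0.105, gamma = 0.013 kcal/(mol A^2) and
# C = -2.89 kcal/mol are the published SIE parametrisation and are the
# package defaults.

COULOMB_K <- 332.0636  # kcal A / (mol e^2)

#' SIE coefficients
#'
#' @param alpha global scaling coefficient (dimensionless).
#' @param gamma cavity coefficient in kcal/(mol Angstrom^2).
#' @param constant additive constant C in kcal/mol.
#' @return an object of class `sie_coefficients`.
#' @export
sie_coefficients <- function(alpha = 0.105, gamma = 0.013, constant = -2.89) {
  if (alpha <= 0) stop_config("'alpha' must be > 0")
  structure(list(alpha = alpha, gamma = gamma, constant = constant),
            class = "sie_coefficients")
}

#' Lennard-Jones 12-6 pair energy
#'
#' Lorentz-Berthelot combination: `rmin = rmin_i_half + rmin_j_half`,
#' `eps = sqrt(eps_i * eps_j)`; the minimum is `-eps` at `r = rmin`.
#'
#' @param rmin_i_half,rmin_j_half per-atom rmin/2 in Angstrom.
#' @param eps_i,eps_j per-atom well depths in kcal/mol.
#' @param r interatomic distance in Angstrom (> 0).
#' @return pair energy in kcal/mol.
#' @export
lj_energy <- function(rmin_i_half, eps_i, rmin_j_half, eps_j, r) {
  if (any(r <= 0)) stop_data("Lennard-Jones energy undefined at r <= 0")
  rmin <- rmin_i_half + rmin_j_half
  eps <- sqrt(eps_i * eps_j)
  sr6 <- (rmin / r)^6
  eps * (sr6^2 - 2 * sr6)
}

#' Coulomb pair energy
#'
#' @param qi,qj partial charges in elementary-charge units.
#' @param r distance in Angstrom (> 0).
#' @param dielectric relative dielectric constant (> 0).
#' @return pair energy in kcal/mol (`332.0636 qi qj / (eps r)`).
#' @export
coulomb_energy <- function(qi, qj, r, dielectric = 1) {
  if (any(r <= 0)) stop_data("Coulomb energy undefined at r <= 0")
  if (dielectric <= 0) stop_data("dielectric must be > 0")
  COULOMB_K * qi * qj / (dielectric * r)
}

check_parameterised <- function(top, idx) {
  at <- top$atoms
  bad <- idx[!is.finite(at$charge[idx]) | !is.finite(at$rmin_half[idx]) |
             !is.finite(at$epsilon[idx])]
  if (length(bad))
    stop_data("unparameterised atom(s): %s",
              paste(utils::head(bad, 10), collapse = ", "))
}

#' Intermolecular Lennard-Jones and Coulomb energies
#'
#' Sums over all receptor-ligand atom pairs with no cutoff and a vacuum
#' dielectric of 1 (analysis energies, not the engine's truncated ones).
#'
#' @param coords N x 3 frame coordinates.
#' @param top parameterised [topology()] with disjoint groups.
#' @param receptor,ligand group names or atom-index vectors.
#' @return named numeric vector `c(e_vdw =, e_ele =)` in kcal/mol.
#' @export
intermolecular_terms <- function(coords, top, receptor = "receptor",
                                 ligand = "ligand") {
  ri <- group_indices(top, receptor)
  li <- group_indices(top, ligand)
  if (length(intersect(ri, li))) stop_data("groups overlap")
  check_parameterised(top, c(ri, li))
  at <- top$atoms
  r <- cross_dist(coords[ri, , drop = FALSE], coords[li, , drop = FALSE])
  if (any(r == 0)) stop_data("coincident receptor/ligand atoms (r = 0)")
  rmin <- outer(at$rmin_half[ri], at$rmin_half[li], "+")
  eps <- sqrt(outer(at$epsilon[ri], at$epsilon[li]))
  sr6 <- (rmin / r)^6
  e_vdw <- sum(eps * (sr6^2 - 2 * sr6))
  e_ele <- COULOMB_K * sum(outer(at$charge[ri], at$charge[li]) / r)
  c(e_vdw = e_vdw, e_ele = e_ele)
}

# Generalized-Born pair function of Still and co-workers.
gb_f <- function(r2, ai, aj) {
  aa <- ai * aj
  sqrt(r2 + aa * exp(-r2 / (4 * aa)))
}

#' Generalized-Born reaction-field (polar solvation) energy
#'
#' Still-type pairwise generalized-Born energy of a charge set with fixed
#' Born radii:
#' `-166.0318 (1/eps_in - 1/eps_out) * sum_ij qi qj / f_ij` over all ordered
#' pairs, with `f_ii = a_i`, so an isolated ion reduces to the Born formula
#' `-166.0318 q^2 (1/eps_in - 1/eps_out) / a`.
#'
#' @param charges partial charges (e).
#' @param born_radii per-atom Born radii in Angstrom (> 0).
#' @param positions N x 3 coordinates.
#' @param eps_in interior dielectric (default 2.25, matching the SIE
#'   parametrisation the default coefficients were calibrated with).
#' @param eps_out solvent dielectric (default 78.5).
#' @return solvation energy in kcal/mol.
#' @export
born_reaction_field <- function(charges, born_radii, positions,
                                eps_in = 2.25, eps_out = 78.5) {
  if (!(eps_out > eps_in && eps_in >= 1))
    stop_data("need eps_out > eps_in >= 1")
  if (any(!is.finite(born_radii) | born_radii <= 0))
    stop_data("non-positive Born radius")
  n <- length(charges)
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) != n || length(born_radii) != n)
    stop_data("charges, radii and positions disagree in length")
  pref <- -(COULOMB_K / 2) * (1 / eps_in - 1 / eps_out)
  r2 <- cross_dist(positions, positions)^2
  f <- gb_f(r2, matrix(born_radii, n, n),
            matrix(born_radii, n, n, byrow = TRUE))
  pref * sum(outer(charges, charges) / f)
}

# Receptor-ligand cross part of the GB energy: with rigid groups and fixed
# Born radii, GB(complex) - GB(receptor) - GB(ligand) reduces exactly to
# twice the cross-pair sum (the self and intra-group terms cancel).
gb_cross_matrix <- function(coords, top, eps_in, eps_out) {
  ri <- top$groups$receptor; li <- top$groups$ligand
  at <- top$atoms
  a_r <- at$born_radius[ri]; a_l <- at$born_radius[li]
  if (any(!is.finite(c(a_r, a_l)) | c(a_r, a_l) <= 0))
    stop_data("missing Born radii on receptor/ligand atoms")
  pref <- -(COULOMB_K / 2) * (1 / eps_in - 1 / eps_out)
  r2 <- cross_dist(coords[ri, , drop = FALSE], coords[li, , drop = FALSE])^2
  f <- gb_f(r2, matrix(a_r, length(a_r), length(a_l)),
            matrix(a_l, length(a_r), length(a_l), byrow = TRUE))
  2 * pref * outer(at$charge[ri], at$charge[li]) / f
}

#' Reaction-field change upon binding (GB surrogate)
#'
#' @param coords N x 3 frame coordinates.
#' @param top parameterised [topology()] with groups and Born radii.
#' @param eps_in,eps_out dielectrics as in [born_reaction_field()].
#' @return `G_RF = GB(complex) - GB(receptor) - GB(ligand)` in kcal/mol.
#' @export
reaction_field_delta <- function(coords, top, eps_in = 2.25, eps_out = 78.5) {
  if (!(eps_out > eps_in && eps_in >= 1))
    stop_data("need eps_out > eps_in >= 1")
  sum(gb_cross_matrix(coords, top, eps_in, eps_out))
}

#' Cavity (nonpolar solvation) term
#'
#' @param delta_sasa buried surface area on binding,
#'   `SASA(complex) - SASA(receptor) - SASA(ligand)`, in Angstrom^2
#'   (negative for burial).
#' @param gamma surface-tension coefficient in kcal/(mol Angstrom^2).
#' @return `gamma * delta_sasa` in kcal/mol.
#' @export
cavity_term <- function(delta_sasa, gamma = 0.013) gamma * delta_sasa

#' Combine SIE components into a binding free energy
#'
#' `dG = alpha * (e_vdw + cavity + e_ele + g_rf) + C`.  The component
#' arguments are vectorised, so a table of per-snapshot or per-system
#' component means can be combined in one call.
#'
#' @param e_vdw,e_ele,g_rf,cavity component energies in kcal/mol (the
#'   cavity argument is the already-scaled `gamma*dSA` term).
#' @param coeffs a [sie_coefficients()].
#' @return binding free energy estimate(s) in kcal/mol.
#' @export
sie_combine <- function(e_vdw, e_ele, g_rf, cavity,
                        coeffs = sie_coefficients()) {
  stopifnot(all(is.finite(c(e_vdw, e_ele, g_rf, cavity))))
  coeffs$alpha * (e_vdw + cavity + e_ele + g_rf) + coeffs$constant
}

#' Evenly spaced snapshot indices within a window
#'
#' First and last frame of the window are always included.
#'
#' @param window integer frame indices.
#' @param n number of snapshots.
#' @return integer frame indices of length `n`.
#' @export
snapshot_frames <- function(window, n = 100L) {
  if (length(window) < n)
    stop_data("window has %d frames; %d snapshots requested",
              length(window), n)
  if (n == 1L) return(window[1])
  window[unique(round(seq(1, length(window), length.out = n)))]
}

#' SIE binding free energy from a trajectory
#'
#' Computes the four SIE components on evenly spaced snapshots from the
#' analysis window (100 snapshots from the equilibrated tail by default)
#' and combines them per snapshot; reports the per-snapshot table and the
#' mean and standard deviation of the estimate.
#'
#' @param traj parameterised [trajectory()] with groups.
#' @param coeffs a [sie_coefficients()].
#' @param window integer frame indices (default: [tail_window()] of 10%).
#' @param n_snapshots snapshots drawn from the window (default 100).
#' @param sasa a [sasa_params()] for the cavity term.
#' @param eps_in,eps_out GB dielectrics for the reaction-field term.
#' @return object of class `sie_result`: list with `per_snapshot` (data
#'   frame of components and `dg_bind` per frame), `mean`, `sd`, `coeffs`.
#' @export
sie_from_trajectory <- function(traj, coeffs = sie_coefficients(),
                                window = NULL, n_snapshots = 100L,
                                sasa = sasa_params(), eps_in = 2.25,
                                eps_out = 78.5) {
  window <- window %||% tail_window(traj)
  frames <- snapshot_frames(window, n_snapshots)
  top <- traj$topology
  ri <- top$groups$receptor; li <- top$groups$ligand
  rows <- lapply(frames, function(f) {
    m <- frame_coords(traj, f)
    inter <- intermolecular_terms(m, top)
    g_rf <- reaction_field_delta(m, top, eps_in, eps_out)
    a_all <- shrake_rupley_sasa(m, params = sasa, top = top)
    a_rec <- shrake_rupley_sasa(m[ri, , drop = FALSE],
                                radii = top$atoms$vdw_radius[ri], params = sasa)
    a_lig <- shrake_rupley_sasa(m[li, , drop = FALSE],
                                radii = top$atoms$vdw_radius[li], params = sasa)
    dsa <- sum(a_all) - sum(a_rec) - sum(a_lig)
    cav <- cavity_term(dsa, coeffs$gamma)
    c(inter["e_vdw"], inter["e_ele"], g_rf = g_rf, cavity = cav,
      delta_sasa = dsa)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab$frame <- frames
  tab$time_ps <- traj$times[frames]
  tab$dg_bind <- sie_combine(tab$e_vdw, tab$e_ele, tab$g_rf, tab$cavity,
                             coeffs)
  structure(list(per_snapshot = tab[, c("frame", "time_ps", "e_vdw", "e_ele",
                                        "g_rf", "cavity", "delta_sasa",
                                        "dg_bind")],
                 mean = mean(tab$dg_bind),
                 sd = stats::sd(tab$dg_bind),
                 coeffs = coeffs),
            class = "sie_result")
}

#' @export
print.sie_result <- function(x, ...) {
  cat(sprintf("SIE binding free energy: %.2f +/- %.2f kcal/mol (%d snapshots)\n",
              x$mean, if (is.na(x$sd)) 0 else x$sd, nrow(x$per_snapshot)))
  invisible(x)
}

#' Per-residue decomposition of the binding energy
#'
#' For each receptor residue, averages over window snapshots: the
#' residue-ligand Lennard-Jones energy plus the residue's share of the
#' nonpolar (buried-surface) term as `vdw_term`, and the residue-ligand
#' Coulomb energy plus the residue's pairwise share of the GB polar
#' solvation change as `ele_term`.  The pairwise vdW/Coulomb parts sum over
#' residues to the corresponding intermolecular totals exactly.
#'
#' @param traj parameterised [trajectory()] with groups.
#' @param window integer frame indices (default: [tail_window()]).
#' @param n_snapshots snapshots drawn from the window (default 100, capped
#'   at the window length).
#' @param gamma cavity coefficient for the nonpolar share.
#' @param sasa a [sasa_params()].
#' @param eps_in,eps_out GB dielectrics.
#' @param key_threshold kcal/mol; residues strictly below it are flagged
#'   (default -1.00).
#' @return data frame of class `residue_decomposition`: `resno`, `resname`,
#'   `vdw_term`, `ele_term`, `total`, `is_key`, plus pairwise-only columns
#'   `pair_vdw` and `pair_ele` used by the conservation check.
#' @export
per_residue_decomposition <- function(traj, window = NULL,
                                      n_snapshots = 100L, gamma = 0.013,
                                      sasa = sasa_params(), eps_in = 2.25,
                                      eps_out = 78.5, key_threshold = -1.0) {
  window <- window %||% tail_window(traj)
  n_snapshots <- min(n_snapshots, length(window))
  frames <- snapshot_frames(window, n_snapshots)
  top <- traj$topology
  ri <- top$groups$receptor; li <- top$groups$ligand
  check_parameterised(top, c(ri, li))
  at <- top$atoms
  res_of <- at$resno[ri]
  resnos <- sort(unique(res_of))
  acc <- matrix(0, length(resnos), 4,
                dimnames = list(NULL, c("pair_vdw", "pair_ele", "polar",
                                        "nonpolar")))
  rmin <- outer(at$rmin_half[ri], at$rmin_half[li], "+")
  eps <- sqrt(outer(at$epsilon[ri], at$epsilon[li]))
  qq <- COULOMB_K * outer(at$charge[ri], at$charge[li])
  for (f in frames) {
    m <- frame_coords(traj, f)
    r <- cross_dist(m[ri, , drop = FALSE], m[li, , drop = FALSE])
    if (any(r == 0)) stop_data("coincident atoms in frame %d", f)
    sr6 <- (rmin / r)^6
    vdw_atom <- rowSums(eps * (sr6^2 - 2 * sr6))
    ele_atom <- rowSums(qq / r)
    gb_atom <- rowSums(gb_cross_matrix(m, top, eps_in, eps_out))
    a_cplx <- shrake_rupley_sasa(m, params = sasa, top = top, subset = ri)
    a_rec <- shrake_rupley_sasa(m[ri, , drop = FALSE],
                                radii = at$vdw_radius[ri], params = sasa)
    dsa_atom <- a_cplx[ri] - a_rec
    for (k in seq_along(resnos)) {
      sel <- res_of == resnos[k]
      acc[k, ] <- acc[k, ] + c(sum(vdw_atom[sel]), sum(ele_atom[sel]),
                               sum(gb_atom[sel]),
                               gamma * sum(dsa_atom[sel]))
    }
  }
  acc <- acc / length(frames)
  out <- data.frame(resno = resnos,
                    resname = at$resname[ri][match(resnos, res_of)],
                    vdw_term = acc[, "pair_vdw"] + acc[, "nonpolar"],
                    ele_term = acc[, "pair_ele"] + acc[, "polar"],
                    pair_vdw = acc[, "pair_vdw"],
                    pair_ele = acc[, "pair_ele"])
  out$total <- out$vdw_term + out$ele_term
  out$is_key <- out$total < key_threshold
  class(out) <- c("residue_decomposition", "data.frame")
  out
}

#' Key binding residues
#'
#' Residues whose decomposed contribution stabilises the complex by more
#' than the threshold, i.e. `total < threshold` strictly (a residue at
#' exactly the threshold is excluded).
#'
#' @param decomposition output of [per_residue_decomposition()].
#' @param threshold kcal/mol (default -1.00).
#' @return the qualifying rows, sorted by `total` ascending.
#' @export
key_residues <- function(decomposition, threshold = -1.0) {
  keep <- decomposition[decomposition$total < threshold, , drop = FALSE]
  keep[order(keep$total), , drop = FALSE]
}
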