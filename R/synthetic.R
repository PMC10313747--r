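# Seeded synthetic-data generators.
#
# The generators produce topologies and trajectories with the statistical
# structure the analysis assumes -- a receptor whose two gate loops switch
# between a closed (~19 A) and an open (~22 A) centroid-separation basin, a
# pocket ligand with scripted hydrogen-bond occupancies and a controlled
# atom-contact count, and per-residue positional fluctuations -- so every
# pipeline stage can be validated against known ground truth without any
# external download.  They are pure functions of (parameters, seed).

LJ_PARAMS <- list(
  rmin_half = c(C = 1.908, N = 1.824, O = 1.661, H = 0.600),
  epsilon   = c(C = 0.1094, N = 0.170, O = 0.210, H = 0.0157),
  vdw       = c(C = 1.70, N = 1.55, O = 1.52, H = 1.20))

orthonormal_frame <- function(g) {
  g <- g / sqrt(sum(g^2))
  ref <- if (abs(g[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * g) * g
  u <- u / sqrt(sum(u^2))
  v <- c(g[2] * u[3] - g[3] * u[2], g[3] * u[1] - g[1] * u[3],
         g[1] * u[2] - g[2] * u[1])
  list(g = g, u = u, v = v)
}

toy_layout <- function(n_residues, contact_atoms) {
  p <- min(contact_atoms, max(2L, n_residues - 2L * 11L - 4L))
  loop_len <- min(11L, max(2L, (n_residues - p - 2L) %/% 2L))
  loopA <- (p + 2L):(p + 1L + loop_len)
  loopB <- (p + 3L + loop_len):(p + 2L + 2L * loop_len)
  list(pocket = seq_len(p), donor_res = p + 1L, loopA = loopA,
       acceptor_res = max(loopA) + 1L, loopB = loopB,
       scaffold = setdiff(seq_len(n_residues),
                          c(seq_len(p), p + 1L, loopA, max(loopA) + 1L,
                            loopB)))
}

# distance from point t*g to the nearest row of `pts`
ray_min_dist <- function(t, g, pts) {
  min(sqrt(dist2_point(t * g, pts)))
}

#' Build a synthetic receptor-ligand complex
#'
#' Constructs a CA-trace-plus-dummy-sidechain receptor around a small
#' pocket ligand: a ring of pocket residues whose CB atoms sit at a fixed
#' 3.05 A from the ligand (setting the resting atom-contact count with
#' margin against frame jitter), two gate
#' loops whose CA centroids sit `gate_distance` apart, a serine-like donor
#' residue above the pocket and a backbone-acceptor residue below it (the
#' anchors used by [script_ligand_interactions()]), and scaffold residues on
#' an outer ring.  All atoms carry charges, Lennard-Jones parameters and
#' radii.
#'
#' @param n_residues receptor residue count (>= 10; >= 44 for the full
#'   default pocket and 11-residue loops).
#' @param seed integer seed (scaffold placement noise); the same seed gives
#'   byte-identical output.
#' @param contact_atoms number of receptor atoms placed in resting contact
#'   (< 3.5 A) with the ligand.
#' @param gate_distance loop CA-centroid separation in the reference frame
#'   (Angstrom).
#' @param receptor_net_charge,ligand_net_charge optional target group net
#'   charges; partial charges are shifted uniformly to meet them.
#' @return object of class `toy_complex`: list with `topology` (groups and
#'   parameters assigned, layout metadata in `attr(, "toy_meta")`),
#'   `coords` (N x 3), `param_table`.
#' @export
make_toy_complex <- function(n_residues = 50L, seed = 1L,
                             contact_atoms = 17L, gate_distance = 22.0,
                             receptor_net_charge = NULL,
                             ligand_net_charge = NULL) {
  n_residues <- as.integer(n_residues)
  contact_atoms <- as.integer(contact_atoms)
  if (n_residues < 10L) stop_config("'n_residues' must be >= 10")
  lay <- toy_layout(n_residues, contact_atoms)
  p <- length(lay$pocket)

  ## ligand: 8-carbon ring + apex carbon + carbonyl O1 + hydroxyl O2-H2
  ang <- 2 * pi * (0:7) / 8
  lig_xyz <- rbind(cbind(1.8 * cos(ang), 1.8 * sin(ang), 0),
                   c(0, 0, 1.6),          # C9 apex
                   c(2.6, 0, 0.4),        # O1 acceptor
                   c(-2.6, 0, 0.4),       # O2 hydroxyl
                   c(-3.4, 0, 0.95))      # H2 (0.97 A from O2)
  h2 <- lig_xyz[12, ] - lig_xyz[11, ]
  lig_xyz[12, ] <- lig_xyz[11, ] + 0.97 * h2 / sqrt(sum(h2^2))
  lig_names <- c(paste0("C", 1:8), "C9", "O1", "O2", "H2")
  lig_el <- c(rep("C", 9), "O", "O", "H")
  lig_charge <- c(0.30, rep(0, 3), 0.30, rep(0, 3), 0, -0.45, -0.55, 0.40)
  # contact placement anchors on the static ring/apex carbons only: the two
  # oxygens are repositioned every frame by the interaction script
  lig_static <- lig_xyz[1:9, , drop = FALSE]

  res_atoms <- list(); res_info <- list()
  add_res <- function(resno, resname, names, els, xyz, charges) {
    res_atoms[[length(res_atoms) + 1L]] <<-
      list(resno = resno, resname = resname, names = names, els = els,
           xyz = xyz, charges = charges)
  }
  backbone <- function(ca, g, u, extra_names = NULL, extra_xyz = NULL,
                       extra_el = NULL, extra_q = NULL, cb = NULL) {
    n_pos <- ca + 0.8 * g + 1.2 * u
    list(names = c("N", "H", "CA", "CB", "O", extra_names),
         els = c("N", "H", "C", "C", "O", extra_el),
         xyz = rbind(n_pos, n_pos + 0.98 * g, ca,
                     if (is.null(cb)) ca + 0.7 * g - 1.2 * u else cb,
                     ca + 1.4 * u - 0.5 * g, extra_xyz),
         charges = c(-0.40, 0.30, 0.35, 0.05, -0.30, extra_q))
  }

  ## pocket residues: CB in contact with the ligand, equatorial directions
  dirs <- sphere_points(6L * p)
  dirs <- dirs[abs(dirs[, 3]) < 0.5, , drop = FALSE][seq_len(p), , drop = FALSE]
  for (k in seq_len(p)) {
    fr <- orthonormal_frame(dirs[k, ])
    t_k <- stats::uniroot(function(t) ray_min_dist(t, fr$g, lig_static) - 3.05,
                          c(0.1, 15))$root
    cb <- t_k * fr$g
    ca <- (t_k + 1.5) * fr$g
    bb <- backbone(ca, fr$g, fr$u, cb = cb)
    add_res(lay$pocket[k], "LEU", bb$names, bb$els, bb$xyz, bb$charges)
  }

  ## donor residue (serine-like OG-HG) above the pocket, pointing down
  fr_up <- orthonormal_frame(c(0, 0, 1))
  ca_up <- c(0, 0, 6.7)
  og <- c(0, 0, 5.2); hg <- og - c(0, 0, 0.97)
  bb <- backbone(ca_up, fr_up$g, fr_up$u, extra_names = c("OG", "HG"),
                 extra_xyz = rbind(og, hg), extra_el = c("O", "H"),
                 extra_q = c(-0.60, 0.45))
  bb$charges[3] <- 0.50  # CA compensates the hydroxyl pair
  add_res(lay$donor_res, "SER", bb$names, bb$els, bb$xyz, bb$charges)

  ## acceptor residue below the pocket: its backbone O is the scripted
  ## acceptor for the ligand hydroxyl donor
  fr_dn <- orthonormal_frame(c(0, 0, -1))
  ca_dn <- c(0, 0, -5.5)
  bb <- backbone(ca_dn, fr_dn$g, fr_dn$u)
  bb$xyz[5, ] <- c(0, 0, -4.0)  # backbone O toward the ligand
  add_res(lay$acceptor_res, "THR", bb$names, bb$els, bb$xyz, bb$charges)

  ## gate loops along y at +/- gate_distance/2 in x, raised above the pocket
  loop_xyz <- function(range, xc) {
    L <- length(range)
    for (j in seq_along(range)) {
      ca <- c(xc, (j - (L + 1) / 2) * 1.5, 8.0)
      g <- c(sign(xc), 0, 0)
      fr <- orthonormal_frame(g)
      bb <- backbone(ca, fr$g, fr$u)
      add_res(range[j], "VAL", bb$names, bb$els, bb$xyz, bb$charges)
    }
  }
  loop_xyz(lay$loopA, -gate_distance / 2)
  loop_xyz(lay$loopB, +gate_distance / 2)

  ## scaffold ring
  scaffold_noise <- with_seed(seed,
    matrix(stats::rnorm(3 * max(1, length(lay$scaffold)), 0, 0.3), ncol = 3))
  for (j in seq_along(lay$scaffold)) {
    a <- 2 * pi * (j - 0.5) / max(1, length(lay$scaffold))
    ca <- c(16 * cos(a), 16 * sin(a), -2) + scaffold_noise[j, ]
    fr <- orthonormal_frame(ca - c(0, 0, -2))
    bb <- backbone(ca, fr$g, fr$u)
    add_res(lay$scaffold[j], "ALA", bb$names, bb$els, bb$xyz, bb$charges)
  }

  ## assemble in residue order, ligand last
  res_atoms <- res_atoms[order(vapply(res_atoms, `[[`, integer(1), "resno"))]
  names_all <- character(); els <- character(); resno <- integer()
  resname <- character(); xyz <- NULL; q <- numeric()
  bonds <- NULL
  for (r in res_atoms) {
    base <- length(names_all)
    names_all <- c(names_all, r$names); els <- c(els, r$els)
    resno <- c(resno, rep(r$resno, length(r$names)))
    resname <- c(resname, rep(r$resname, length(r$names)))
    xyz <- rbind(xyz, r$xyz); q <- c(q, r$charges)
    # N-H, N-CA, CA-CB, CA-O (+ CB-OG, OG-HG for the serine)
    b <- rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5))
    if (length(r$names) == 7L) b <- rbind(b, c(4, 6), c(6, 7))
    bonds <- rbind(bonds, b + base)
  }
  base <- length(names_all)
  names_all <- c(names_all, lig_names); els <- c(els, lig_el)
  resno <- c(resno, rep(n_residues + 1L, length(lig_names)))
  resname <- c(resname, rep("LIG", length(lig_names)))
  xyz <- rbind(xyz, lig_xyz); q <- c(q, lig_charge)
  ring <- cbind(1:8, c(2:8, 1))
  bonds <- rbind(bonds, ring + base,
                 base + rbind(c(1, 9), c(1, 10), c(5, 11), c(11, 12)))

  at <- data.frame(serial = seq_along(names_all), name = names_all,
                   element = els, resname = resname, resno = resno,
                   chain = "A", stringsAsFactors = FALSE)
  at$charge <- q
  at$rmin_half <- LJ_PARAMS$rmin_half[els]
  at$epsilon <- LJ_PARAMS$epsilon[els]
  at$vdw_radius <- LJ_PARAMS$vdw[els]
  at$born_radius <- LJ_PARAMS$vdw[els]
  top <- topology(at, bonds = bonds)
  top <- assign_groups(top, "LIG")
  if (!is.null(receptor_net_charge)) {
    idx <- top$groups$receptor
    top$atoms$charge[idx] <- top$atoms$charge[idx] +
      (receptor_net_charge - sum(top$atoms$charge[idx])) / length(idx)
  }
  if (!is.null(ligand_net_charge)) {
    idx <- top$groups$ligand
    top$atoms$charge[idx] <- top$atoms$charge[idx] +
      (ligand_net_charge - sum(top$atoms$charge[idx])) / length(idx)
  }

  find_atom <- function(rn, nm) which(top$atoms$resno == rn &
                                      top$atoms$name == nm)
  meta <- list(
    loopA_range = sprintf("%d-%d", min(lay$loopA), max(lay$loopA)),
    loopB_range = sprintf("%d-%d", min(lay$loopB), max(lay$loopB)),
    pocket_residues = lay$pocket,
    contact_atoms = p,
    gate_distance = gate_distance,
    ligand_base = unname(lig_xyz),
    receptor_base = unname(xyz),
    pairs = list(
      list(type = "receptor_donor",
           donor = find_atom(lay$donor_res, "OG"),
           hydrogen = find_atom(lay$donor_res, "HG"),
           acceptor = find_atom(n_residues + 1L, "O1")),
      list(type = "ligand_donor",
           donor = find_atom(n_residues + 1L, "O2"),
           hydrogen = find_atom(n_residues + 1L, "H2"),
           acceptor = find_atom(lay$acceptor_res, "O"))))
  attr(top, "toy_meta") <- meta
  param_cols <- c("serial", "charge", "rmin_half", "epsilon", "vdw_radius",
                  "born_radius")
  structure(list(topology = top, coords = unname(xyz),
                 param_table = top$atoms[, param_cols]),
            class = c("toy_complex", "mdstructure"))
}

#' Gate-dynamics parameters
#'
#' @param n_frames number of frames (default 30000, i.e. a 300 ns run at
#'   10 ps spacing).
#' @param basin_means closed/open loop-separation means in Angstrom.
#' @param basin_sigmas within-basin standard deviations in Angstrom.
#' @param switch_prob overall per-frame switching scale in \[0, 1); 0
#'   freezes the chain in its start state.
#' @param occupancy_target stationary open-state fraction.
#' @param jitter_sigma per-coordinate Gaussian jitter (Angstrom) applied to
#'   every atom each frame.
#' @param loop_jitter_sigma jitter for gate-loop residues (default: same).
#' @param dt_ps frame spacing in ps.
#' @param start_state `"stationary"`, `"close"`, or `"open"`.
#' @param seed integer seed.
#' @return an object of class `gate_params`.
#' @export
gate_params <- function(n_frames = 30000L, basin_means = c(19.0, 22.0),
                        basin_sigmas = c(0.4, 0.4), switch_prob = 0.2,
                        occupancy_target = 0.5, jitter_sigma = 0.15,
                        loop_jitter_sigma = NULL, dt_ps = 10,
                        start_state = "stationary", seed = 1L) {
  if (length(basin_means) != 2L || basin_means[1] == basin_means[2])
    stop_config("'basin_means' must be two distinct values (close, open)")
  if (switch_prob < 0 || switch_prob >= 1)
    stop_config("'switch_prob' must be in [0, 1)")
  if (occupancy_target <= 0 || occupancy_target >= 1)
    stop_config("'occupancy_target' must be in (0, 1)")
  structure(list(n_frames = as.integer(n_frames),
                 basin_means = basin_means, basin_sigmas = basin_sigmas,
                 switch_prob = switch_prob,
                 occupancy_target = occupancy_target,
                 jitter_sigma = jitter_sigma,
                 loop_jitter_sigma = loop_jitter_sigma %||% jitter_sigma,
                 dt_ps = dt_ps, start_state = start_state,
                 seed = as.integer(seed)),
            class = "gate_params")
}

#' Simulate a two-state gate trajectory
#'
#' The gate separation follows a two-state Markov chain (closed/open basins
#' with Gaussian within-basin noise) whose stationary open fraction is
#' `occupancy_target`; the two loops are displaced symmetrically along the
#' gate axis to realise each frame's separation, and every atom receives
#' independent Gaussian jitter.  Kinetics are deliberately Markovian, not
#' Langevin: the analysis consumes only the stationary distribution and the
#' switching structure.
#'
#' @param complex a [make_toy_complex()] result (or any `mdstructure` whose
#'   topology carries `toy_meta` loop ranges).
#' @param params a [gate_params()].
#' @return a [trajectory()]; attributes `gate_state` (per-frame
#'   `"close"`/`"open"`) and `gate_distance` carry the ground truth.
#' @export
simulate_gate_trajectory <- function(complex, params = gate_params()) {
  top <- complex$topology
  meta <- attr(top, "toy_meta")
  if (is.null(meta)) stop_data("topology lacks gate-loop metadata")
  coords0 <- complex$coords
  ia <- resolve_selection(selection(meta$loopA_range), top)
  ib <- resolve_selection(selection(meta$loopB_range), top)
  ca_a <- colMeans(coords0[intersect(ia, which(top$atoms$name == "CA")), ,
                           drop = FALSE])
  ca_b <- colMeans(coords0[intersect(ib, which(top$atoms$name == "CA")), ,
                           drop = FALSE])
  d_ref <- sqrt(sum((ca_b - ca_a)^2))
  u <- (ca_b - ca_a) / d_ref
  nf <- params$n_frames
  n <- n_atoms(top)
  f_open <- params$occupancy_target
  p_co <- min(1, 2 * params$switch_prob * f_open)        # close -> open
  p_oc <- min(1, 2 * params$switch_prob * (1 - f_open))  # open -> close

  out <- with_seed(params$seed, {
    s0 <- switch(params$start_state,
                 stationary = if (stats::runif(1) < f_open) 2L else 1L,
                 close = 1L, open = 2L,
                 stop_config("unknown start_state '%s'", params$start_state))
    flips <- stats::runif(nf)
    states <- integer(nf); states[1] <- s0
    for (f in seq_len(nf - 1L)) {
      p <- if (states[f] == 1L) p_co else p_oc
      states[f + 1L] <- if (flips[f] < p) 3L - states[f] else states[f]
    }
    d_t <- params$basin_means[states] +
      stats::rnorm(nf, 0, params$basin_sigmas[states])
    sd_atom <- rep(params$jitter_sigma, n)
    sd_atom[c(ia, ib)] <- params$loop_jitter_sigma
    arr <- aperm(array(t(coords0), c(3, n, nf)), c(3, 2, 1))
    arr <- arr + array(stats::rnorm(nf * n * 3, 0,
                                    rep(rep(sd_atom, each = nf), 3)),
                       c(nf, n, 3))
    shift <- (d_t - d_ref) / 2
    for (cc in 1:3) {
      arr[, ib, cc] <- arr[, ib, cc] + shift * u[cc]
      arr[, ia, cc] <- arr[, ia, cc] - shift * u[cc]
    }
    list(arr = arr, states = states, d_t = d_t)
  })
  traj <- trajectory(top, out$arr, times = (seq_len(nf) - 1) * params$dt_ps)
  attr(traj, "gate_state") <- c("close", "open")[out$states]
  attr(traj, "gate_distance") <- out$d_t
  traj
}

#' Ligand-scripting parameters
#'
#' @param occupancies per-pair hydrogen-bond occupancy fractions in
#'   \[0, 1\] (recycled over the topology's scripted pairs).
#' @param contact_count_target intended mean atom-contact count; the
#'   resting pocket supplies `target - 1` contacts and each engaged
#'   scripted bond adds one, keeping the series within +/- 2.
#' @param jitter_sigma Gaussian jitter (Angstrom) on non-scripted ligand
#'   atoms.
#' @param seed integer seed.
#' @return an object of class `ligand_script_params`.
#' @export
ligand_script_params <- function(occupancies = c(0.7, 0.4),
                                 contact_count_target = 18L,
                                 jitter_sigma = 0.05, seed = 1L) {
  if (any(occupancies < 0 | occupancies > 1))
    stop_config("occupancies must lie in [0, 1]")
  structure(list(occupancies = occupancies,
                 contact_count_target = as.integer(contact_count_target),
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "ligand_script_params")
}

#' Script ligand interactions onto a trajectory
#'
#' For each scripted donor/hydrogen/acceptor triple (defined by the toy
#' complex), each frame independently engages the bond with the pair's
#' target occupancy.  Engagement places the mobile partner exactly on the
#' donor-hydrogen axis at a compliant 2.80 A donor-acceptor distance
#' (angle 180 degrees); disengagement places it at 4.30 A, violating the
#' distance criterion outright.  The receptor-side anchor atoms of each
#' pair are held at their reference positions (exempt from frame jitter) so
#' the scripted geometry, and hence the frame-level truth label, is exact
#' by construction rather than by energy minimisation.
#'
#' @param traj a [trajectory()] over a toy-complex topology.
#' @param params a [ligand_script_params()].
#' @return the trajectory with ligand atoms rewritten; attribute
#'   `hbond_truth` holds the per-pair engagement matrix (frames x pairs).
#' @export
script_ligand_interactions <- function(traj, params = ligand_script_params()) {
  top <- traj$topology
  meta <- attr(top, "toy_meta")
  if (is.null(meta) || !length(top$groups$ligand))
    stop_data("trajectory lacks a scripted ligand")
  pairs <- meta$pairs
  occ <- rep(params$occupancies, length.out = length(pairs))
  nf <- n_frames(traj)
  lig <- top$groups$ligand
  scripted_atoms <- unlist(lapply(pairs, function(pr)
    c(pr$donor, pr$hydrogen, pr$acceptor)))
  free_lig <- setdiff(lig, scripted_atoms)
  arr <- traj$coords
  # un-jittered ligand template, indexed like the ligand group
  base_lig <- meta$ligand_base
  lig_pos <- match(free_lig, lig)
  truth <- with_seed(params$seed, {
    engaged <- vapply(occ, function(p) stats::runif(nf) < p,
                      logical(nf))
    engaged <- matrix(engaged, nrow = nf)
    jit <- array(stats::rnorm(nf * length(free_lig) * 3, 0,
                              params$jitter_sigma),
                 c(nf, length(free_lig), 3))
    for (cc in 1:3)
      arr[, free_lig, cc] <- matrix(base_lig[lig_pos, cc],
                                    nf, length(free_lig), byrow = TRUE) +
        jit[, , cc]
    rec_base <- meta$receptor_base
    lig_ctr <- colMeans(base_lig[lig_pos, , drop = FALSE])
    pin <- function(idx) {
      for (cc in 1:3) arr[, idx, cc] <<- rec_base[idx, cc]
    }
    place <- function(idx, origin, axis, dist) {
      for (cc in 1:3)
        arr[, idx, cc] <<- origin[cc] + axis[cc] * dist
    }
    for (k in seq_along(pairs)) {
      pr <- pairs[[k]]
      dist_on <- ifelse(engaged[, k], 2.8, 4.3)
      if (pr$type == "receptor_donor") {
        # anchors: receptor donor and hydrogen; mobile: the ligand acceptor
        pin(pr$donor); pin(pr$hydrogen)
        axis <- rec_base[pr$hydrogen, ] - rec_base[pr$donor, ]
        axis <- axis / sqrt(sum(axis^2))
        place(pr$acceptor, rec_base[pr$donor, ], axis, dist_on)
      } else {
        # anchor: receptor acceptor; mobile: ligand donor and its hydrogen
        pin(pr$acceptor)
        w <- lig_ctr - rec_base[pr$acceptor, ]
        w <- w / sqrt(sum(w^2))
        place(pr$donor, rec_base[pr$acceptor, ], w, dist_on)
        place(pr$hydrogen, rec_base[pr$acceptor, ], w, dist_on - 0.97)
      }
    }
    engaged
  })
  out <- trajectory(top, arr, traj$times)
  attr(out, "gate_state") <- attr(traj, "gate_state")
  attr(out, "gate_distance") <- attr(traj, "gate_distance")
  attr(out, "hbond_truth") <- truth
  out
}
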