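# Atom contacts, geometric hydrogen bonds, occupancy statistics, and
# per-residue interaction maps.

#' Atom-contact criteria
#'
#' @param cutoff Angstrom distance cutoff (default 3.50): a receptor atom is
#'   "in contact" when its minimum distance to any ligand atom is at or
#'   below the cutoff.
#' @param heavy_atoms_only drop hydrogens from both groups before counting
#'   (default `TRUE`).
#' @return an object of class `contact_criteria`.
#' @export
contact_criteria <- function(cutoff = 3.5, heavy_atoms_only = TRUE) {
  check_numeric_scalar(cutoff, "cutoff", positive = TRUE)
  structure(list(cutoff = cutoff, heavy_atoms_only = isTRUE(heavy_atoms_only)),
            class = "contact_criteria")
}

#' Hydrogen-bond criteria
#'
#' Geometric definition: donor-acceptor distance at or below
#' `max_da_distance` and donor-H-acceptor angle (measured at the hydrogen)
#' at or above `min_dha_angle`; both boundaries inclusive.
#'
#' @param max_da_distance Angstrom (default 3.50).
#' @param min_dha_angle degrees (default 150.00).
#' @return an object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 150.0) {
  check_numeric_scalar(max_da_distance, "max_da_distance", positive = TRUE)
  if (min_dha_angle <= 0 || min_dha_angle > 180)
    stop_config("'min_dha_angle' must be in (0, 180]")
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

group_indices <- function(top, group) {
  idx <- if (is.character(group)) top$groups[[group]] else as.integer(group)
  if (is.null(idx) || !length(idx))
    stop_data("empty or unknown atom group")
  idx
}

#' Count receptor atoms in contact with the ligand
#'
#' @param coords N x 3 frame coordinates.
#' @param top a [topology()] with receptor/ligand groups.
#' @param criteria a [contact_criteria()].
#' @param receptor,ligand group names or atom-index vectors.
#' @return integer: number of receptor atoms whose minimum distance to any
#'   ligand atom is at or below the cutoff.
#' @export
atom_contacts <- function(coords, top, criteria = contact_criteria(),
                          receptor = "receptor", ligand = "ligand") {
  ri <- group_indices(top, receptor)
  li <- group_indices(top, ligand)
  if (length(intersect(ri, li)))
    stop_data("receptor and ligand groups overlap")
  if (criteria$heavy_atoms_only) {
    ri <- ri[top$atoms$element[ri] != "H"]
    li <- li[top$atoms$element[li] != "H"]
  }
  if (!length(ri) || !length(li)) return(0L)
  d <- cross_dist(coords[ri, , drop = FALSE], coords[li, , drop = FALSE])
  sum(apply(d, 1, min) <= criteria$cutoff)
}

# Donor-hydrogen covalent pairs: N/O atoms bonded to an H.
donor_h_pairs <- function(top, within) {
  if (is.null(top$bonds) || !nrow(top$bonds))
    stop_data("topology has no bond list; cannot identify donor-H pairs")
  el <- top$atoms$element
  b <- top$bonds
  keep1 <- el[b[, 1]] %in% c("N", "O") & el[b[, 2]] == "H"
  keep2 <- el[b[, 2]] %in% c("N", "O") & el[b[, 1]] == "H"
  dh <- rbind(b[keep1, , drop = FALSE], b[keep2, 2:1, drop = FALSE])
  dh[dh[, 1] %in% within, , drop = FALSE]
}

hb_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Detect geometric hydrogen bonds in a frame
#'
#' Donors are N/O atoms (within `donors_from`) covalently bonded to a
#' hydrogen; acceptors are N/O atoms within `acceptors_from`.  Sulfur is not
#' considered.  An event requires both criteria of [hbond_criteria()].
#'
#' @param coords N x 3 frame coordinates.
#' @param top a [topology()] carrying a bond list.
#' @param donors_from,acceptors_from group names or atom-index vectors to
#'   draw donors/acceptors from.
#' @param criteria an [hbond_criteria()].
#' @return data frame with one row per event: `donor`, `hydrogen`,
#'   `acceptor` (atom indices), `distance_A`, `angle_deg`.
#' @export
detect_hbonds <- function(coords, top, donors_from = "receptor",
                          acceptors_from = "ligand",
                          criteria = hbond_criteria()) {
  di <- group_indices(top, donors_from)
  ai <- group_indices(top, acceptors_from)
  el <- top$atoms$element
  acceptors <- ai[el[ai] %in% c("N", "O")]
  dh <- donor_h_pairs(top, di)
  events <- list()
  for (k in seq_len(nrow(dh))) {
    d <- dh[k, 1]; h <- dh[k, 2]
    cand <- acceptors[acceptors != d & acceptors != h]
    if (!length(cand)) next
    dist_da <- sqrt(dist2_point(coords[d, ], coords[cand, , drop = FALSE]))
    cand <- cand[dist_da <= criteria$max_da_distance]
    dist_da <- dist_da[dist_da <= criteria$max_da_distance]
    for (j in seq_along(cand)) {
      ang <- hb_angle(coords[d, ], coords[h, ], coords[cand[j], ])
      if (ang >= criteria$min_dha_angle)
        events[[length(events) + 1L]] <-
          data.frame(donor = d, hydrogen = h, acceptor = cand[j],
                     distance_A = dist_da[j], angle_deg = ang)
    }
  }
  if (!length(events))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance_A = numeric(),
                      angle_deg = numeric()))
  do.call(rbind, events)
}

#' Hydrogen-bond occupancy of a donor/acceptor pair
#'
#' Percentage of frames in the window in which any hydrogen of the donor
#' satisfies the geometric criteria with the acceptor.
#'
#' @param traj a [trajectory()].
#' @param donor,acceptor atom indices (1-based rows of the atom table).
#' @param criteria an [hbond_criteria()].
#' @param window integer frame indices (default: all frames).
#' @return occupancy percentage in \[0, 100\].
#' @export
hbond_occupancy <- function(traj, donor, acceptor,
                            criteria = hbond_criteria(), window = NULL) {
  window <- window %||% seq_len(n_frames(traj))
  if (!length(window)) stop_data("empty frame window")
  top <- traj$topology
  dh <- donor_h_pairs(top, donor)
  if (!nrow(dh)) stop_data("atom %d has no bonded hydrogen", donor)
  present <- vapply(window, function(f) {
    m <- frame_coords(traj, f)
    for (k in seq_len(nrow(dh))) {
      d <- dh[k, 1]; h <- dh[k, 2]
      r <- sqrt(sum((m[d, ] - m[acceptor, ])^2))
      if (r <= criteria$max_da_distance &&
          hb_angle(m[d, ], m[h, ], m[acceptor, ]) >= criteria$min_dha_angle)
        return(TRUE)
    }
    FALSE
  }, logical(1))
  100 * mean(present)
}

#' Per-frame contact and H-bond count series
#'
#' @param traj a [trajectory()] with receptor/ligand groups and bonds.
#' @param contact a [contact_criteria()].
#' @param hbond an [hbond_criteria()].
#' @param frames optional integer frame indices.
#' @return data frame with `frame`, `time_ps`, `n_contacts`, `n_hbonds`
#'   (H-bonds counted in both donor directions).
#' @export
interaction_series <- function(traj, contact = contact_criteria(),
                               hbond = hbond_criteria(), frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  out <- vapply(frames, function(f) {
    m <- frame_coords(traj, f)
    nc <- atom_contacts(m, top, contact)
    nh <- nrow(detect_hbonds(m, top, "receptor", "ligand", hbond)) +
          nrow(detect_hbonds(m, top, "ligand", "receptor", hbond))
    c(nc, nh)
  }, numeric(2))
  data.frame(frame = frames, time_ps = traj$times[frames],
             n_contacts = as.integer(out[1, ]),
             n_hbonds = as.integer(out[2, ]))
}

#' Per-residue interaction-occurrence map
#'
#' For every receptor residue that comes within the contact cutoff of the
#' ligand at any point in the window, reports the percentage of window
#' frames with (a) at least one geometric H-bond between that residue and
#' the ligand (either donor direction) and (b) at least one carbon-carbon
#' contact at or below the cutoff (hydrophobic contact).
#'
#' @param traj a [trajectory()] with groups and bonds.
#' @param contact a [contact_criteria()].
#' @param hbond an [hbond_criteria()].
#' @param window integer frame indices (default: all frames).
#' @return data frame with `resno`, `resname`, `hbond_pct`,
#'   `hydrophobic_pct`; empty when nothing is ever in contact.
#' @export
interaction_map <- function(traj, contact = contact_criteria(),
                            hbond = hbond_criteria(), window = NULL) {
  window <- window %||% seq_len(n_frames(traj))
  if (!length(window)) stop_data("empty frame window")
  top <- traj$topology
  rec <- top$groups$receptor; lig <- group_indices(top, "ligand")
  resno <- top$atoms$resno
  el <- top$atoms$element
  rec_c <- rec[el[rec] == "C"]; lig_c <- lig[el[lig] == "C"]
  seen <- integer(); hb_hits <- list(); ph_hits <- list()
  for (f in window) {
    m <- frame_coords(traj, f)
    d <- cross_dist(m[rec, , drop = FALSE], m[lig, , drop = FALSE])
    near <- rec[apply(d, 1, min) <= contact$cutoff]
    seen <- union(seen, unique(resno[near]))
    ev <- rbind(detect_hbonds(m, top, "receptor", "ligand", hbond),
                detect_hbonds(m, top, "ligand", "receptor", hbond))
    hb_res <- integer()
    if (nrow(ev)) {
      res_atoms <- ifelse(ev$donor %in% rec, ev$donor, ev$acceptor)
      hb_res <- unique(resno[res_atoms])
    }
    ph_res <- integer()
    if (length(rec_c) && length(lig_c)) {
      dc <- cross_dist(m[rec_c, , drop = FALSE], m[lig_c, , drop = FALSE])
      ph_res <- unique(resno[rec_c[apply(dc, 1, min) <= contact$cutoff]])
    }
    hb_hits[[length(hb_hits) + 1L]] <- hb_res
    ph_hits[[length(ph_hits) + 1L]] <- ph_res
  }
  seen <- sort(seen)
  if (!length(seen))
    return(data.frame(resno = integer(), resname = character(),
                      hbond_pct = numeric(), hydrophobic_pct = numeric()))
  hb_pct <- vapply(seen, function(r)
    100 * mean(vapply(hb_hits, function(v) r %in% v, logical(1))), numeric(1))
  ph_pct <- vapply(seen, function(r)
    100 * mean(vapply(ph_hits, function(v) r %in% v, logical(1))), numeric(1))
  resname <- top$atoms$resname[match(seen, resno)]
  data.frame(resno = seen, resname = resname, hbond_pct = hb_pct,
             hydrophobic_pct = ph_pct)
}

#' Frame window covering the final fraction of a trajectory
#'
#' The analysis window defaults to the last tenth of the run (the
#' equilibrated tail, e.g. the last 10 ns of a 100 ns production segment).
#'
#' @param traj a [trajectory()].
#' @param fraction final fraction of frames to keep (default 0.1).
#' @return integer frame indices.
#' @export
tail_window <- function(traj, fraction = 0.1) {
  if (fraction <= 0 || fraction > 1)
    stop_config("'fraction' must be in (0, 1]")
  nf <- n_frames(traj)
  n <- max(1L, ceiling(nf * fraction))
  seq.int(nf - n + 1L, nf)
}
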