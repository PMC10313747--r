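# Superposition and deviation/fluctuation metrics.

#' Open/close gate thresholds
#'
#' The gate loops populate two basins of centroid separation, near 19 A
#' (closed) and 22 A (open); the classification boundary defaults to their
#' 20.5 A midpoint, with ties assigned to the open state.
#'
#' @param d_open open-basin distance in Angstrom.
#' @param d_close closed-basin distance in Angstrom.
#' @param boundary decision boundary in Angstrom.
#' @return an object of class `conformation_thresholds`.
#' @export
conformation_thresholds <- function(d_open = 22.0, d_close = 19.0,
                                    boundary = (d_open + d_close) / 2) {
  if (!(d_close < boundary && boundary < d_open))
    stop_config("need d_close < boundary < d_open")
  structure(list(d_open = d_open, d_close = d_close, boundary = boundary),
            class = "conformation_thresholds")
}

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD of `mobile` onto `reference`; reflections are disallowed
#' by construction (sign-corrected SVD).
#'
#' @param mobile N x 3 coordinate matrix.
#' @param reference N x 3 coordinate matrix, matched atom order.
#' @param weights optional non-negative per-atom weights.
#' @return list of class `superposition` with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), and `rmsd` (Angstrom); transformed
#'   coordinates are `mobile %*% rotation` plus the translation, see
#'   [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n)
    stop_data("superposition needs matched coordinate sets with N >= 3")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop_data("invalid superposition weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sv_p <- svd(P)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1e-30))
    stop_data("ill-conditioned superposition: collinear coordinates")
  H <- crossprod(P * w, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  R <- t(R)  # so that rotated = P %*% R
  fitted <- P %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = cr - as.numeric(cm %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param coords M x 3 matrix (any atoms, not only the fitted set).
#' @param fit a `superposition` from [kabsch_superpose()].
#' @return transformed M x 3 matrix.
#' @export
apply_superposition <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, -fit$translation)
}

rmsd_pair <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series
#'
#' Each frame is superposed on the reference over `fit_sel` (receptor CA by
#' default) and the RMSD is measured over `measure_sel`.
#'
#' @param traj a [trajectory()].
#' @param reference N x 3 reference coordinates for the full system; default
#'   is the first frame.
#' @param fit_sel [selection()] used for the superposition (default: all
#'   CA atoms).
#' @param measure_sel [selection()] the deviation is measured over
#'   (default: the fit selection).
#' @return data frame with `frame`, `time_ps`, `rmsd_A`.
#' @export
rmsd_series <- function(traj, reference = NULL,
                        fit_sel = selection("all", atoms = "CA"),
                        measure_sel = fit_sel) {
  top <- traj$topology
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  if (nrow(reference) != n_atoms(top))
    stop_data("reference has %d atoms; trajectory has %d",
              nrow(reference), n_atoms(top))
  fi <- resolve_selection(fit_sel, top)
  mi <- resolve_selection(measure_sel, top)
  ref_fit <- reference[fi, , drop = FALSE]
  ref_meas <- reference[mi, , drop = FALSE]
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    fit <- kabsch_superpose(m[fi, , drop = FALSE], ref_fit)
    rmsd_pair(apply_superposition(m[mi, , drop = FALSE], fit), ref_meas)
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times,
             rmsd_A = out)
}

#' Per-residue RMSF
#'
#' Frames are superposed on `fit_sel` against the first frame, the
#' time-average structure of the measured atoms is formed, and the root
#' mean square fluctuation about that average is reported per residue
#' (CA-only by default, so one atom per residue).
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param sel [selection()] of measured atoms (default: all CA).
#' @param fit_sel [selection()] used for superposition (default: all CA).
#' @return data frame with `resno`, `resname`, `rmsf_A`.
#' @export
rmsf_per_residue <- function(traj, sel = selection("all", atoms = "CA"),
                             fit_sel = selection("all", atoms = "CA")) {
  if (n_frames(traj) < 2L)
    stop_data("RMSF needs at least 2 frames")
  top <- traj$topology
  fi <- resolve_selection(fit_sel, top)
  si <- resolve_ca(sel, top)
  ref_fit <- frame_coords(traj, 1)[fi, , drop = FALSE]
  nf <- n_frames(traj)
  stack <- array(NA_real_, c(nf, length(si), 3))
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    fit <- kabsch_superpose(m[fi, , drop = FALSE], ref_fit)
    stack[f, , ] <- apply_superposition(m[si, , drop = FALSE], fit)
  }
  avg <- apply(stack, c(2, 3), mean)
  dev2 <- matrix(0, nf, length(si))
  avg <- matrix(avg, ncol = 3)
  for (f in seq_len(nf))
    dev2[f, ] <- rowSums((matrix(stack[f, , ], ncol = 3) - avg)^2)
  rmsf_atom <- sqrt(colMeans(dev2))
  at <- top$atoms[si, ]
  agg <- stats::aggregate(rmsf_atom,
                          by = list(resno = at$resno, resname = at$resname),
                          FUN = mean)
  agg <- agg[order(agg$resno), ]
  data.frame(resno = agg$resno, resname = agg$resname, rmsf_A = agg$x,
             row.names = NULL)
}

#' Centroid-centroid distance series between two selections
#'
#' The distance reported per frame is between the unweighted centroids of
#' the two resolved atom sets (the gate-loop pipeline passes CA-only
#' selections).
#'
#' @param traj a [trajectory()].
#' @param selA,selB [selection()]s for the two groups.
#' @return data frame with `frame`, `time_ps`, `distance_A`.
#' @export
centroid_distance_series <- function(traj, selA, selB) {
  top <- traj$topology
  ia <- resolve_selection(selA, top)
  ib <- resolve_selection(selB, top)
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    ca <- colMeans(m[ia, , drop = FALSE])
    cb <- colMeans(m[ib, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times,
             distance_A = d)
}

#' Classify gate conformation from loop separation
#'
#' @param distance numeric vector of loop centroid separations (Angstrom).
#' @param thresholds a [conformation_thresholds()].
#' @return character vector of `"open"`/`"close"` labels (distances at the
#'   boundary count as open).
#' @export
classify_conformation <- function(distance,
                                  thresholds = conformation_thresholds()) {
  if (any(distance <= 0)) stop_data("distances must be positive")
  ifelse(distance >= thresholds$boundary, "open", "close")
}
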