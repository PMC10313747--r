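# Two-dimensional free-energy landscape by Boltzmann inversion of the joint
# histogram over (gate-loop distance, gate-loop RMSD), with basin detection
# and open/close classification.
#
# With g(x, y) the normalised joint probability over the two reaction
# coordinates, the landscape is dG(x, y) = -kB T ln(g / g_max): the most
# populated bin sits at zero and every occupied bin is non-negative.  Empty
# bins are masked (NA), not infinite.

#' FEL parameters
#'
#' @param bin_width_x,bin_width_y histogram bin widths in Angstrom
#'   (default 0.10 for both coordinates).
#' @param temperature simulation temperature in K (default 310.00).
#' @param kB Boltzmann constant in kcal/(mol K).
#' @return an object of class `fel_params`.
#' @export
fel_params <- function(bin_width_x = 0.10, bin_width_y = 0.10,
                       temperature = 310.0, kB = 0.0019872041) {
  check_numeric_scalar(bin_width_x, "bin_width_x", positive = TRUE)
  check_numeric_scalar(bin_width_y, "bin_width_y", positive = TRUE)
  check_numeric_scalar(temperature, "temperature", positive = TRUE)
  structure(list(bin_width_x = bin_width_x, bin_width_y = bin_width_y,
                 temperature = temperature, kB = kB),
            class = "fel_params")
}

#' Build a 2D free-energy landscape
#'
#' Histograms the two coordinate series on zero-anchored bin edges (edges at
#' integer multiples of the bin width, so grids are reproducible across
#' runs), normalises to a joint probability, and Boltzmann-inverts relative
#' to the most populated bin.
#'
#' @param x,y equal-length coordinate series in Angstrom.
#' @param params a [fel_params()].
#' @return object of class `fel_grid`: list with `x_edges`, `y_edges`,
#'   `x_centers`, `y_centers`, `counts`, `probability`, `free_energy`
#'   (kcal/mol, NA in empty bins), `params`.
#' @export
build_fel <- function(x, y, params = fel_params()) {
  if (!length(x) || length(x) != length(y))
    stop_data("x and y must be non-empty series of equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_data("non-finite reaction-coordinate values")
  wx <- params$bin_width_x; wy <- params$bin_width_y
  ix <- floor(x / wx); iy <- floor(y / wy)
  lx <- min(ix):max(ix); ly <- min(iy):max(iy)
  counts <- table(factor(ix, levels = lx), factor(iy, levels = ly))
  counts <- matrix(as.numeric(counts), length(lx), length(ly))
  prob <- counts / sum(counts)
  fe <- -params$kB * params$temperature * log(prob / max(prob))
  fe[counts == 0] <- NA_real_
  structure(list(x_edges = c(lx, max(lx) + 1) * wx,
                 y_edges = c(ly, max(ly) + 1) * wy,
                 x_centers = (lx + 0.5) * wx,
                 y_centers = (ly + 0.5) * wy,
                 counts = counts, probability = prob, free_energy = fe,
                 params = params),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat(sprintf("FEL grid %d x %d bins (%d occupied), max dG %.2f kcal/mol\n",
              length(x$x_centers), length(x$y_centers), occ,
              max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' Detect basins on a free-energy landscape
#'
#' A basin candidate is an occupied bin whose free energy does not exceed
#' any of its 8 occupied neighbours.  Connected candidate plateaus (equal
#' depth) collapse to their lowest-(x, y)-index bin, and representatives
#' closer than `min_separation_bins` (Chebyshev distance) merge into the
#' deeper one.
#'
#' Isolated, barely populated bins in the tail of a finite-sample histogram
#' would otherwise qualify as minima (an empty neighbourhood never vetoes),
#' so candidates deeper than `max_depth` above the global minimum are
#' discarded; the default keeps bins holding at least 5% of the modal bin's
#' probability (`kB T ln 20`, about 1.85 kcal/mol at 310 K).
#'
#' @param grid a [build_fel()] grid.
#' @param min_separation_bins merge radius in bins (default 10, i.e. 1 A at the default bin width).
#' @param max_depth depth cutoff in kcal/mol for basin candidates
#'   (default `kB T ln 20`).
#' @return data frame with `x_center`, `y_center`, `depth` (kcal/mol),
#'   sorted by depth ascending (global minimum first).
#' @export
find_basins <- function(grid, min_separation_bins = 10L, max_depth = NULL) {
  fe <- grid$free_energy
  nx <- nrow(fe); ny <- ncol(fe)
  if (!any(!is.na(fe))) stop_data("grid has no occupied bins")
  max_depth <- max_depth %||%
    (grid$params$kB * grid$params$temperature * log(20))
  # pad with +Inf so edges and masked neighbours never veto a minimum
  pad <- matrix(Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- ifelse(is.na(fe), Inf, fe)
  is_min <- matrix(TRUE, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
    is_min <- is_min & (pad[2:(nx + 1), 2:(ny + 1)] <= nb)
  }
  is_min <- is_min & !is.na(fe) & fe <= max_depth
  cand <- which(is_min, arr.ind = TRUE)
  if (!nrow(cand)) stop_data("no basin candidates found")
  # group connected equal-depth candidates (plateaus) by union-find
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  depth <- fe[cand]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (max(abs(cand[i, ] - cand[j, ])) <= 1 &&
        isTRUE(all.equal(depth[i], depth[j])))
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(unique(roots), function(r) {
    members <- which(roots == r)
    members[order(cand[members, 1], cand[members, 2])][1]
  }, integer(1))
  # merge representatives within the separation radius, keeping the deeper
  ord <- reps[order(depth[reps], cand[reps, 1], cand[reps, 2])]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) ||
        all(vapply(kept, function(k)
          max(abs(cand[i, ] - cand[k, ])) > min_separation_bins, logical(1))))
      kept <- c(kept, i)
  }
  data.frame(x_center = grid$x_centers[cand[kept, 1]],
             y_center = grid$y_centers[cand[kept, 2]],
             depth = depth[kept])
}

#' Gate-loop free-energy landscape pipeline
#'
#' Computes the two reaction coordinates from a trajectory -- the CA-centroid
#' separation of the two gate loops (x) and the joint RMSD of both loops'
#' CA atoms against the first frame after superposition on the receptor CA
#' set (y) -- builds the landscape, detects basins, and labels every frame
#' open or close from the distance coordinate.
#'
#' @param traj a [trajectory()].
#' @param loopA,loopB [selection()]s for the two gate loops (CA atoms are
#'   used).
#' @param params a [fel_params()].
#' @param thresholds a [conformation_thresholds()].
#' @param fit_sel [selection()] for the pre-RMSD superposition (default:
#'   all CA atoms).
#' @param min_separation_bins basin merge radius (see [find_basins()]).
#' @return object of class `fel_result`: list with `grid`, `basins`,
#'   `labels` (per-frame open/close), `x`, `y` series.
#' @export
fel_pipeline <- function(traj, loopA, loopB, params = fel_params(),
                         thresholds = conformation_thresholds(),
                         fit_sel = selection("all", atoms = "CA"),
                         min_separation_bins = 10L) {
  if (is.character(loopA)) loopA <- selection(loopA)
  if (is.character(loopB)) loopB <- selection(loopB)
  if (is.null(loopA$atoms)) loopA$atoms <- "CA"
  if (is.null(loopB$atoms)) loopB$atoms <- "CA"
  x <- centroid_distance_series(traj, loopA, loopB)$distance_A
  top <- traj$topology
  ia <- resolve_selection(loopA, top)
  ib <- resolve_selection(loopB, top)
  loops_idx <- sort(union(ia, ib))
  fi <- resolve_selection(fit_sel, top)
  ref <- frame_coords(traj, 1)
  y <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    fit <- kabsch_superpose(m[fi, , drop = FALSE], ref[fi, , drop = FALSE])
    rmsd_pair(apply_superposition(m[loops_idx, , drop = FALSE], fit),
              ref[loops_idx, , drop = FALSE])
  }, numeric(1))
  grid <- build_fel(x, y, params)
  basins <- find_basins(grid, min_separation_bins)
  labels <- classify_conformation(x, thresholds)
  structure(list(grid = grid, basins = basins, labels = labels,
                 x = x, y = y),
            class = "fel_result")
}

#' Export a FEL grid as a tidy table
#'
#' @param grid a [build_fel()] grid.
#' @return data frame with `x_center`, `y_center`, `count`, `probability`,
#'   `free_energy_kcal_mol`; masked (empty) bins are omitted.
#' @export
fel_grid_table <- function(grid) {
  occ <- which(grid$counts > 0, arr.ind = TRUE)
  occ <- occ[order(occ[, 1], occ[, 2]), , drop = FALSE]
  data.frame(x_center = grid$x_centers[occ[, 1]],
             y_center = grid$y_centers[occ[, 2]],
             count = grid$counts[occ],
             probability = grid$probability[occ],
             free_energy_kcal_mol = grid$free_energy[occ])
}
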