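# Shared data model and file I/O.
#
# A `topology` holds the ordered atom table (one row per atom, with force-field
# parameters once assigned), the covalent bond list, and named atom groups
# ("receptor", "ligand").  Coordinates live outside the topology: a single
# conformation is an N x 3 matrix in Angstrom; a `trajectory` stacks F frames
# into an F x N x 3 array with per-frame times in ps.

#' Construct a topology
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain` and (optionally populated) parameter columns
#'   `charge`, `rmin_half`, `epsilon`, `vdw_radius`, `born_radius`.
#' @param bonds two-column integer matrix of atom indices (1-based rows of
#'   `atoms`), or `NULL` for no bond information.
#' @param groups named list of integer atom-index vectors; the pipeline uses
#'   the names `"receptor"` and `"ligand"`, which must be disjoint.
#' @return an object of class `topology`.
#' @export
topology <- function(atoms, bonds = NULL, groups = list()) {
  required <- c("serial", "name", "element", "resname", "resno", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop_data("atom table lacks columns: %s", paste(missing_cols, collapse = ", "))
  for (col in c("charge", "rmin_half", "epsilon", "vdw_radius", "born_radius"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (any(atoms$resno < 1L))
    stop_data("residue numbers must be >= 1 (1-based author numbering)")
  n <- nrow(atoms)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) && (min(bonds) < 1L || max(bonds) > n))
      stop_data("bond indices outside 1..%d", n)
    bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  }
  if (!is.null(groups$receptor) && !is.null(groups$ligand) &&
      length(intersect(groups$receptor, groups$ligand)))
    stop_data("'receptor' and 'ligand' groups must be disjoint")
  structure(list(atoms = atoms, bonds = bonds, groups = groups),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d bonds\n",
              nrow(x$atoms), length(unique(x$atoms$resno)),
              if (is.null(x$bonds)) 0L else nrow(x$bonds)))
  for (g in names(x$groups))
    cat(sprintf("  group '%s': %d atoms\n", g, length(x$groups[[g]])))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Construct a trajectory
#'
#' @param topology a [topology()].
#' @param coords F x N x 3 array of coordinates in Angstrom (N = atom count).
#' @param times numeric vector of F frame times in ps; defaults to 10 ps
#'   spacing starting at 0.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL) {
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L)
    stop_data("coords must be an F x N x 3 array")
  if (d[2] != n_atoms(topology))
    stop_data("frame width %d does not match atom count %d",
              d[2], n_atoms(topology))
  if (any(!is.finite(coords)))
    stop_data("non-finite coordinates in trajectory")
  if (is.null(times)) times <- (seq_len(d[1]) - 1) * 10
  if (length(times) != d[1] || any(diff(times) <= 0))
    stop_data("times must have one strictly increasing value per frame")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %.1f-%.1f ps\n",
              dim(x$coords)[1], dim(x$coords)[2],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Assign receptor/ligand groups by residue name
#'
#' Atoms whose residue name is listed in `ligand_resnames` form the
#' `"ligand"` group; all remaining atoms form the `"receptor"` group.
#'
#' @param top a [topology()].
#' @param ligand_resnames character vector of ligand residue names.
#' @return the topology with `groups$receptor` and `groups$ligand` set.
#' @export
assign_groups <- function(top, ligand_resnames) {
  lig <- which(top$atoms$resname %in% ligand_resnames)
  rec <- setdiff(seq_len(n_atoms(top)), lig)
  top$groups$receptor <- rec
  top$groups$ligand <- lig
  top
}

guess_element <- function(name) {
  # PDB convention: a leading digit (e.g. "1HG1") still names a hydrogen;
  # otherwise the first alphabetic character is the element for organic atoms.
  stripped <- sub("^[0-9]+", "", trimws(name))
  toupper(substr(stripped, 1, 1))
}

validate_pdb_lines <- function(lines, path) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    stop_data("malformed ATOM/HETATM record at line %d of '%s' (too short)",
              bad[1], path)
  for (i in which(rec)) {
    xyz <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
             substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop_data("malformed coordinates at line %d of '%s'", i, path)
  }
  invisible(TRUE)
}

parse_conect <- function(lines, serials) {
  con <- lines[grepl("^CONECT", lines)]
  if (!length(con)) return(NULL)
  idx_of <- match(seq_len(max(serials)), serials)  # serial -> row index
  pairs <- list()
  for (ln in con) {
    flds <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                                 "\\s+")[[1]]))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 2) next
    a <- idx_of[flds[1]]
    for (b in idx_of[flds[-1]])
      if (!is.na(a) && !is.na(b))
        pairs[[length(pairs) + 1L]] <- sort(c(a, b))
  }
  if (!length(pairs)) return(NULL)
  m <- unique(do.call(rbind, pairs))
  m
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (through bio3d) plus CONECT records.  A
#' single-model file returns a structure (topology plus one conformation); a
#' multi-model file returns a [trajectory()] with one frame per MODEL and
#' default 10 ps frame spacing.
#'
#' @param path PDB file path.
#' @param ligand_resnames optional residue names used to populate the
#'   `"ligand"` group (see [assign_groups()]).
#' @return a list of class `mdstructure` with elements `topology` and
#'   `coords` (N x 3), or a `trajectory` for multi-model input.
#' @export
read_pdb <- function(path, ligand_resnames = NULL) {
  if (!file.exists(path)) stop_data("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop_data("no ATOM/HETATM records in '%s'", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  element <- at$elesy
  blank <- is.na(element) | trimws(element) == ""
  element[blank] <- guess_element(at$elety[blank])
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = trimws(element), resname = trimws(at$resid),
                      resno = at$resno, chain = chain,
                      stringsAsFactors = FALSE)
  bonds <- parse_conect(lines, atoms$serial)
  top <- topology(atoms, bonds = bonds)
  if (!is.null(ligand_resnames)) top <- assign_groups(top, ligand_resnames)
  nf <- nrow(pdb$xyz)
  if (is.null(nf) || nf == 1L) {
    coords <- matrix(as.numeric(pdb$xyz), ncol = 3, byrow = TRUE)
    return(structure(list(topology = top, coords = coords),
                     class = "mdstructure"))
  }
  arr <- array(NA_real_, c(nf, nrow(atoms), 3))
  for (f in seq_len(nf))
    arr[f, , ] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(top, arr)
}

#' Write a PDB file
#'
#' Writes a structure as a single model or a trajectory as a multi-model PDB
#' (MODEL/ENDMDL), with CONECT records when the topology carries bonds.
#' Ligand-group atoms are written as HETATM records.
#'
#' @param x an `mdstructure`, a [trajectory()], or a [topology()] (then
#'   `coords` must be given).
#' @param path output file path.
#' @param coords N x 3 matrix, required when `x` is a bare topology.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, coords = NULL) {
  if (inherits(x, "trajectory")) {
    top <- x$topology
    nf <- n_frames(x)
    xyz <- t(apply(x$coords, 1, function(m) as.numeric(t(m))))
  } else if (inherits(x, "mdstructure")) {
    top <- x$topology
    xyz <- matrix(as.numeric(t(x$coords)), nrow = 1)
    nf <- 1L
  } else {
    top <- x
    if (is.null(coords)) stop_data("coords required when writing a topology")
    xyz <- matrix(as.numeric(t(coords)), nrow = 1)
    nf <- 1L
  }
  at <- top$atoms
  type <- rep("ATOM", nrow(at))
  if (length(top$groups$ligand)) type[top$groups$ligand] <- "HETATM"
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz, type = type, eleno = at$serial, elety = at$name,
    resid = at$resname, resno = at$resno, chain = at$chain,
    elesy = at$element, end = TRUE))
  if (!is.null(top$bonds) && nrow(top$bonds)) {
    lines <- readLines(path, warn = FALSE)
    endpos <- max(which(grepl("^END", lines)))
    conect <- sprintf("CONECT%5d%5d",
                      at$serial[top$bonds[, 1]], at$serial[top$bonds[, 2]])
    lines <- append(lines, conect, after = endpos - 1L)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Plain XYZ blocks (`natoms`, comment, one `element x y z` line per atom).
#' A comment of the form `t= <ps>` sets the frame time; otherwise frames are
#' spaced 10 ps apart.
#'
#' @param path XYZ file path.
#' @param top the [topology()] the frames belong to (atom count must match).
#' @return a [trajectory()].
#' @export
read_xyz <- function(path, top) {
  if (!file.exists(path)) stop_data("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- n_atoms(top)
  pos <- 1L
  frames <- list(); times <- numeric()
  while (pos <= length(lines)) {
    hdr <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(hdr) || hdr != n)
      stop_data("XYZ frame at line %d declares %s atoms; topology has %d",
                pos, trimws(lines[pos]), n)
    if (pos + 1L + n > length(lines))
      stop_data("truncated XYZ frame starting at line %d", pos)
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([0-9.eE+-]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    flds <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(flds[, 2:4]), ncol = 3)
    pos <- pos + 2L + n
  }
  if (anyNA(times)) times <- (seq_along(frames) - 1) * 10
  arr <- array(NA_real_, c(length(frames), n, 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  trajectory(top, arr, times)
}

#' Write a multi-frame XYZ trajectory
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  el <- traj$topology$atoms$element
  n <- length(el)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    writeLines(c(sprintf("%d", n), sprintf("t= %.4f", traj$times[f]),
                 sprintf("%-2s %12.6f %12.6f %12.6f",
                         el, m[, 1], m[, 2], m[, 3])), con)
  }
  invisible(path)
}

#' Read a per-atom parameter table
#'
#' A sidecar TSV with columns `serial`, `charge` (e), `rmin_half` (A),
#' `epsilon` (kcal/mol), `vdw_radius` (A), `born_radius` (A), one row per
#' atom, keeps the pipeline engine-agnostic: any force field's assignments
#' can be exported to this format.
#'
#' @param path TSV file path.
#' @param top [topology()] to parameterise.
#' @return the topology with all parameter columns populated.
#' @export
read_parameter_table <- function(path, top) {
  if (!file.exists(path)) stop_data("file not found: '%s'", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("serial", "charge", "rmin_half", "epsilon",
                "vdw_radius", "born_radius")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop_data("parameter table lacks columns: %s", paste(miss, collapse = ", "))
  apply_parameter_table(top, tab)
}

#' Apply an in-memory parameter table to a topology
#'
#' @param top [topology()].
#' @param tab data frame in the [read_parameter_table()] layout.
#' @return the parameterised topology.
#' @export
apply_parameter_table <- function(top, tab) {
  idx <- match(top$atoms$serial, tab$serial)
  if (anyNA(idx))
    stop_data("incomplete parameters: no row for serial(s) %s",
              paste(utils::head(top$atoms$serial[is.na(idx)], 10), collapse = ", "))
  extra <- setdiff(tab$serial, top$atoms$serial)
  if (length(extra))
    stop_data("parameter rows for unknown serial(s) %s",
              paste(utils::head(extra, 10), collapse = ", "))
  for (col in c("charge", "rmin_half", "epsilon", "vdw_radius", "born_radius"))
    top$atoms[[col]] <- as.numeric(tab[[col]][idx])
  if (any(top$atoms$epsilon < 0, na.rm = TRUE))
    stop_data("negative Lennard-Jones epsilon in parameter table")
  if (any(top$atoms$vdw_radius <= 0, na.rm = TRUE))
    stop_data("non-positive van der Waals radius in parameter table")
  top
}

#' Write a per-atom parameter table
#'
#' @param top a parameterised [topology()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(top, path) {
  cols <- c("serial", "charge", "rmin_half", "epsilon",
            "vdw_radius", "born_radius")
  utils::write.table(top$atoms[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Net partial charge of a group
#'
#' @param top parameterised [topology()].
#' @param group group name (e.g. `"receptor"`) or integer atom indices.
#' @return sum of partial charges in elementary-charge units.
#' @export
group_net_charge <- function(top, group) {
  idx <- if (is.character(group)) top$groups[[group]] else group
  if (is.null(idx)) stop_data("unknown group '%s'", group)
  sum(top$atoms$charge[idx])
}
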