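# Residue-range selections.

#' Define an atom selection
#'
#' Selections address atoms by residue ranges in the author numbering taken
#' verbatim from the input file (never renumbered), optionally restricted to
#' a chain and/or to named atoms (e.g. CA only).
#'
#' @param resi residue-range string, e.g. `"83-93"`, `"83-93,100"`, or
#'   `"all"`.
#' @param chain optional single chain identifier.
#' @param atoms optional character vector of atom names to keep (e.g.
#'   `"CA"`).
#' @return an object of class `selection`.
#' @export
selection <- function(resi = "all", chain = NULL, atoms = NULL) {
  if (!is.character(resi) || length(resi) != 1L)
    stop_config("'resi' must be a single residue-range string")
  structure(list(resi = resi, chain = chain, atoms = atoms),
            class = "selection")
}

parse_resi <- function(expr) {
  if (identical(trimws(expr), "all")) return(NULL)  # NULL = no restriction
  parts <- strsplit(gsub("\\s", "", expr), ",")[[1]]
  if (!length(parts)) stop_config("empty residue expression")
  out <- integer()
  for (p in parts) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      if (ab[1] > ab[2])
        stop_config("descending residue range '%s'", p)
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop_config("cannot parse residue expression component '%s'", p)
    }
  }
  sort(unique(out))
}

#' Resolve a selection to atom indices
#'
#' Residue numbers absent from the topology are tolerated (gapped numbering
#' is common in author-numbered structures); an empty result is an error.
#'
#' @param sel a [selection()] (or a residue-range string, promoted with
#'   defaults).
#' @param top a [topology()].
#' @param within optional integer atom indices to intersect with (e.g. a
#'   group).
#' @return sorted, duplicate-free integer atom indices.
#' @export
resolve_selection <- function(sel, top, within = NULL) {
  if (is.character(sel)) sel <- selection(sel)
  at <- top$atoms
  keep <- rep(TRUE, nrow(at))
  resnos <- parse_resi(sel$resi)
  if (!is.null(resnos)) keep <- keep & at$resno %in% resnos
  if (!is.null(sel$chain)) keep <- keep & at$chain == sel$chain
  if (!is.null(sel$atoms)) keep <- keep & at$name %in% sel$atoms
  idx <- which(keep)
  if (!is.null(within)) idx <- intersect(idx, within)
  if (!length(idx))
    stop_data("selection '%s' resolves to no atoms", sel$resi)
  sort(unique(idx))
}

# CA atoms of a selection (used for centroids and fitting); falls back to the
# selection's own atom filter when one is given.
resolve_ca <- function(sel, top, within = NULL) {
  if (is.character(sel)) sel <- selection(sel)
  if (is.null(sel$atoms)) sel$atoms <- "CA"
  resolve_selection(sel, top, within)
}
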