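# Shared fixture builders (everything is generated in code at test time).

# Fixed-width PDB ATOM/HETATM line.
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     el = substr(trimws(name), 1, 1), record = "ATOM  ") {
  sprintf("%s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resn, chain, resno, x, y, z, 1, 0, el)
}

# Minimal parameterised topology: one CA and one CB per residue, on a line.
linear_topology <- function(resnos, spacing = 3.8, charge = 0) {
  n <- length(resnos)
  at <- data.frame(
    serial = seq_len(2 * n),
    name = rep(c("CA", "CB"), n),
    element = "C",
    resname = "ALA",
    resno = rep(resnos, each = 2),
    chain = "A",
    stringsAsFactors = FALSE)
  at$charge <- charge
  at$rmin_half <- 1.908; at$epsilon <- 0.1094
  at$vdw_radius <- 1.7; at$born_radius <- 1.7
  # zig-zag CA trace (non-collinear, as any real backbone is)
  i <- seq_len(n)
  ca <- cbind(i * spacing, (i %% 2) * 1.2, (i %% 3) * 0.8)
  coords <- matrix(NA_real_, 2 * n, 3)
  coords[seq(1, 2 * n, 2), ] <- ca
  coords[seq(2, 2 * n, 2), ] <- sweep(ca, 2, c(0, 1.5, 0), "+")
  list(top = topology(at), coords = coords)
}

# Independent dense-quadrature SASA oracle: random surface points (its own
# point scheme, not the package's lattice).
dense_sasa_oracle <- function(coords, radii, probe = 1.4, n = 1e5,
                              seed = 99) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2))
  re <- radii + probe
  vapply(seq_len(nrow(coords)), function(i) {
    p <- sweep(pts * re[i], 2, coords[i, ], "+")
    buried <- rep(FALSE, n)
    for (j in seq_len(nrow(coords))[-i]) {
      d2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      buried <- buried | d2 < re[j]^2
    }
    mean(!buried) * 4 * pi * re[i]^2
  }, numeric(1))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b),
           a^2 - b^2 - cc^2 + d^2),
         3, 3, byrow = TRUE)
}

# Toy complex with a scripted gate trajectory, shared by several files.
scripted_toy <- function(n_frames = 500, occupancies = c(0.7, 0.4),
                         seed = 1, ...) {
  cx <- make_toy_complex(seed = seed)
  tr <- simulate_gate_trajectory(cx, gate_params(n_frames = n_frames,
                                                 seed = seed + 1, ...))
  tr <- script_ligand_interactions(
    tr, ligand_script_params(occupancies = occupancies, seed = seed + 2))
  list(cx = cx, tr = tr, meta = attr(cx$topology, "toy_meta"))
}
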