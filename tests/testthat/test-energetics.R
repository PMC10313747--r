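test_that("Lennard-Jones pair energy hits well depth and zero crossing", {
  expect_equal(lj_energy(1.9, 0.11, 1.7, 0.21, r = 3.6), -sqrt(0.11 * 0.21))
  expect_equal(lj_energy(1.9, 0.11, 1.7, 0.21, r = 3.6 / 2^(1 / 6)), 0,
               tolerance = 1e-12)
  # scalar oracle on random parameters
  set.seed(4)
  for (i in 1:10) {
    ri <- runif(1, 0.5, 2); rj <- runif(1, 0.5, 2)
    ei <- runif(1, 0.01, 0.3); ej <- runif(1, 0.01, 0.3)
    r <- runif(1, 1, 8)
    eps <- sqrt(ei * ej); rmin <- ri + rj
    expect_equal(lj_energy(ri, ei, rj, ej, r),
                 eps * ((rmin / r)^12 - 2 * (rmin / r)^6), tolerance = 1e-12)
  }
  expect_error(lj_energy(1.9, 0.1, 1.7, 0.2, r = 0),
               class = "sietraj_data_error")
})

test_that("Coulomb energy matches its closed form", {
  expect_equal(coulomb_energy(1, 1, r = 3.320636, dielectric = 1), 100)
  expect_equal(coulomb_energy(0, 1, r = 2), 0)
  expect_equal(coulomb_energy(1, -1, r = 1), -332.0636)
  expect_error(coulomb_energy(1, 1, r = 0), class = "sietraj_data_error")
})

test_that("intermolecular terms vanish at infinite separation and sum pairs", {
  # single-pair system reduces to lj + coulomb
  at <- data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
                   resname = c("ALA", "LIG"), resno = 1:2, chain = "A")
  at$charge <- c(0.3, -0.4); at$rmin_half <- c(1.9, 1.7)
  at$epsilon <- c(0.11, 0.21); at$vdw_radius <- 1.7; at$born_radius <- 1.7
  top <- topology(at, groups = list(receptor = 1L, ligand = 2L))
  co <- rbind(c(0, 0, 0), c(0, 0, 4.2))
  terms <- intermolecular_terms(co, top)
  expect_equal(terms[["e_vdw"]], lj_energy(1.9, 0.11, 1.7, 0.21, 4.2))
  expect_equal(terms[["e_ele"]], coulomb_energy(0.3, -0.4, 4.2))

  # brute-force double-loop oracle on a 10x5 toy
  cx <- make_toy_complex(seed = 3)
  top2 <- cx$topology
  ri <- top2$groups$receptor[1:10]; li <- top2$groups$ligand[1:5]
  top2$groups$receptor <- ri; top2$groups$ligand <- li
  m <- cx$coords
  ev <- 0; ee <- 0
  for (i in ri) for (j in li) {
    r <- sqrt(sum((m[i, ] - m[j, ])^2))
    ev <- ev + lj_energy(top2$atoms$rmin_half[i], top2$atoms$epsilon[i],
                         top2$atoms$rmin_half[j], top2$atoms$epsilon[j], r)
    ee <- ee + coulomb_energy(top2$atoms$charge[i], top2$atoms$charge[j], r)
  }
  terms2 <- intermolecular_terms(m, top2)
  expect_equal(terms2[["e_vdw"]], ev, tolerance = 1e-9)
  expect_equal(terms2[["e_ele"]], ee, tolerance = 1e-9)

  # ligand at 500 A: both terms below 1e-3
  far <- cx$coords
  far[cx$topology$groups$ligand, 1] <- far[cx$topology$groups$ligand, 1] + 500
  terms3 <- intermolecular_terms(far, cx$topology)
  expect_lt(abs(terms3[["e_vdw"]]), 1e-3)
  expect_lt(abs(terms3[["e_ele"]]), 1e-3)
})

test_that("the generalized-Born surrogate reduces to the Born ion and Still form", {
  b <- born_reaction_field(1, 2, matrix(0, 1, 3), eps_in = 1, eps_out = 78.5)
  expect_equal(b, -166.0318 * (1 - 1 / 78.5) / 2, tolerance = 1e-6)
  expect_equal(born_reaction_field(c(0, 0), c(1.5, 2), rbind(c(0, 0, 0),
               c(3, 0, 0))), 0)
  # two-charge system vs an independent evaluation of the Still expression
  q <- c(0.5, -0.8); a <- c(1.6, 2.1)
  pos <- rbind(c(0, 0, 0), c(0, 0, 3.5))
  r2 <- 3.5^2
  fgb <- sqrt(r2 + a[1] * a[2] * exp(-r2 / (4 * a[1] * a[2])))
  pref <- -(332.0636 / 2) * (1 / 2.25 - 1 / 78.5)
  expected <- pref * (q[1]^2 / a[1] + q[2]^2 / a[2] + 2 * q[1] * q[2] / fgb)
  expect_equal(born_reaction_field(q, a, pos), expected, tolerance = 1e-9)
  # symmetric under global charge-sign flip
  expect_equal(born_reaction_field(-q, a, pos),
               born_reaction_field(q, a, pos))
  expect_error(born_reaction_field(1, -1, matrix(0, 1, 3)),
               class = "sietraj_data_error")
  expect_error(born_reaction_field(1, 2, matrix(0, 1, 3), eps_in = 80,
                                   eps_out = 78.5),
               class = "sietraj_data_error")
})

test_that("cavity term scales buried area and is negative on binding", {
  expect_equal(cavity_term(-1000, 0.013), -13.0)
  expect_equal(cavity_term(0), 0)
  cx <- make_toy_complex(seed = 7)
  prm <- sasa_params(n_sphere_points = 240)
  rec <- cx$topology$groups$receptor; lig <- cx$topology$groups$ligand
  a_all <- sum(shrake_rupley_sasa(cx$coords, params = prm, top = cx$topology))
  a_rec <- sum(shrake_rupley_sasa(cx$coords[rec, ],
                                  radii = cx$topology$atoms$vdw_radius[rec],
                                  params = prm))
  a_lig <- sum(shrake_rupley_sasa(cx$coords[lig, ],
                                  radii = cx$topology$atoms$vdw_radius[lig],
                                  params = prm))
  expect_lt(cavity_term(a_all - a_rec - a_lig), 0)
})

test_that("the SIE combiner reproduces worked component examples", {
  # lipid-control replicate 1
  expect_equal(sie_combine(-56.20, -14.40, 19.37, -11.77), -9.505,
               tolerance = 1e-9)
  expect_lte(abs(sie_combine(-56.20, -14.40, 19.37, -11.77) - (-9.49)), 0.02)
  # atovaquone replicate 1
  expect_lte(abs(sie_combine(-28.70, -56.61, 61.96, -5.24) - (-5.89)), 0.01)
  # all-zero components return the constant
  expect_equal(sie_combine(0, 0, 0, 0), -2.89)
  # affine: doubling components doubles (dG - C)
  d1 <- sie_combine(-10, -5, 4, -2) + 2.89
  d2 <- sie_combine(-20, -10, 8, -4) + 2.89
  expect_equal(d2, 2 * d1)
})

test_that("trajectory SIE is consistent, linear, and propagates noise", {
  cx <- make_toy_complex(seed = 2)
  n <- nrow(cx$coords)
  arr <- array(NA_real_, c(3, n, 3))
  for (f in 1:3) arr[f, , ] <- cx$coords
  tr <- trajectory(cx$topology, arr)
  res <- sie_from_trajectory(tr, window = 1:3, n_snapshots = 3,
                             sasa = sasa_params(n_sphere_points = 240))
  expect_equal(res$sd, 0)
  expect_equal(length(unique(round(res$per_snapshot$dg_bind, 9))), 1L)
  # mean of per-snapshot dG equals dG of mean components (linearity)
  sc <- scripted_toy(n_frames = 80, seed = 8)
  res2 <- sie_from_trajectory(sc$tr, window = 1:80, n_snapshots = 10,
                              sasa = sasa_params(n_sphere_points = 240))
  ps <- res2$per_snapshot
  expect_equal(mean(ps$dg_bind),
               sie_combine(mean(ps$e_vdw), mean(ps$e_ele), mean(ps$g_rf),
                           mean(ps$cavity)),
               tolerance = 1e-9)
  expect_error(sie_from_trajectory(sc$tr, window = 1:5, n_snapshots = 10),
               "window", class = "sietraj_data_error")
  # Gaussian component noise with known sigma propagates through the combiner
  set.seed(10)
  nsnap <- 4000
  sig <- c(3, 2.5, 2, 0.5)
  dg <- sie_combine(rnorm(nsnap, -50, sig[1]), rnorm(nsnap, -14, sig[2]),
                    rnorm(nsnap, 19, sig[3]), rnorm(nsnap, -11, sig[4]))
  expect_equal(sd(dg), 0.105 * sqrt(sum(sig^2)), tolerance = 0.1)
})

test_that("per-residue decomposition conserves totals and flags key residues", {
  sc <- scripted_toy(n_frames = 30, seed = 4)
  f <- 30L
  dec <- per_residue_decomposition(sc$tr, window = f, n_snapshots = 1,
                                   sasa = sasa_params(n_sphere_points = 240))
  m <- sc$tr$coords[f, , ]
  terms <- intermolecular_terms(m, sc$tr$topology)
  expect_equal(sum(dec$pair_vdw), terms[["e_vdw"]], tolerance = 1e-6)
  expect_equal(sum(dec$pair_ele), terms[["e_ele"]], tolerance = 1e-6)
  expect_equal(dec$total, dec$vdw_term + dec$ele_term, tolerance = 1e-12)
  expect_identical(dec$is_key, dec$total < -1.0)

  # ligand far away: every residue contributes ~0
  cx <- make_toy_complex(seed = 4)
  far <- cx$coords
  far[cx$topology$groups$ligand, 1] <- far[cx$topology$groups$ligand, 1] + 50
  arr <- array(NA_real_, c(1, nrow(far), 3)); arr[1, , ] <- far
  dec_far <- per_residue_decomposition(trajectory(cx$topology, arr),
                                       window = 1L, n_snapshots = 1,
                                       sasa = sasa_params(n_sphere_points = 240))
  expect_lt(max(abs(dec_far$pair_vdw)), 1e-3)
  expect_true(all(!dec_far$is_key))
})

test_that("a charged residue facing an opposite charge dominates electrostatics", {
  at <- data.frame(serial = 1:3, name = c("CB", "CB", "C1"), element = "C",
                   resname = c("ASP", "ALA", "LIG"), resno = c(1L, 2L, 3L),
                   chain = "A")
  at$charge <- c(-1, 0, 1)
  at$rmin_half <- 1.9; at$epsilon <- 0.11
  at$vdw_radius <- 1.7; at$born_radius <- 1.7
  top <- topology(at, groups = list(receptor = 1:2, ligand = 3L))
  co <- rbind(c(4, 0, 0), c(0, 8, 0), c(0, 0, 0))
  arr <- array(NA_real_, c(1, 3, 3)); arr[1, , ] <- co
  dec <- per_residue_decomposition(trajectory(top, arr), window = 1L,
                                   n_snapshots = 1,
                                   sasa = sasa_params(n_sphere_points = 240))
  expect_lt(dec$ele_term[dec$resno == 1], -10)
  expect_gt(abs(dec$ele_term[dec$resno == 1]),
            10 * abs(dec$ele_term[dec$resno == 2]))
  # hand value for the bare Coulomb part at 4 A
  expect_equal(dec$pair_ele[dec$resno == 1], 332.0636 * (-1) / 4,
               tolerance = 1e-9)
})

test_that("the key-residue filter is strict at the threshold", {
  dec <- data.frame(resno = 1:3, resname = "X",
                    vdw_term = 0, ele_term = 0,
                    total = c(-1.2, -0.8, -3.0))
  dec$is_key <- dec$total < -1
  kr <- key_residues(dec)
  expect_equal(kr$resno, c(3L, 1L))
  expect_equal(nrow(key_residues(transform(dec, total = c(0, 1, 2)))), 0L)
  expect_equal(nrow(key_residues(transform(dec, total = -1.0))), 0L)
})
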