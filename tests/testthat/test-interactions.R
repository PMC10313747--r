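# Hand-built donor(O-H)...acceptor(O) system with controllable geometry.
hb_system <- function(da_dist = 2.8, angle_deg = 180) {
  at <- data.frame(serial = 1:3, name = c("OG", "HG", "O1"),
                   element = c("O", "H", "O"),
                   resname = c("SER", "SER", "LIG"),
                   resno = c(1L, 1L, 2L), chain = "A")
  top <- topology(at, bonds = rbind(c(1, 2)),
                  groups = list(receptor = 1:2, ligand = 3L))
  # donor at origin, H along +x; acceptor position sets the D-H...A angle
  theta <- (180 - angle_deg) * pi / 180
  h <- c(0.97, 0, 0)
  a <- h + (da_dist - 0.97) * c(cos(theta), sin(theta), 0)
  # adjust so the D-A distance (not H-A) equals da_dist when angle != 180
  if (angle_deg != 180) {
    f <- function(s) sqrt(sum((h + s * c(cos(theta), sin(theta), 0))^2)) -
      da_dist
    s <- stats::uniroot(f, c(0.01, 10))$root
    a <- h + s * c(cos(theta), sin(theta), 0)
  }
  list(top = top, coords = rbind(c(0, 0, 0), h, a))
}

test_that("atom contacts count threshold crossings and match brute force", {
  at <- data.frame(serial = 1:4, name = c("C1", "C2", "C3", "CL"),
                   element = "C", resname = c(rep("ALA", 3), "LIG"),
                   resno = c(1:3, 4L), chain = "A")
  top <- topology(at, groups = list(receptor = 1:3, ligand = 4L))
  co <- rbind(c(3.0, 0, 0), c(0, 3.4, 0), c(0, 0, 3.6), c(0, 0, 0))
  expect_equal(atom_contacts(co, top), 2L)
  co_far <- co; co_far[4, ] <- c(50, 0, 0)
  expect_equal(atom_contacts(co_far, top), 0L)
  expect_error(
    atom_contacts(co, top, receptor = 1:3, ligand = 3:4),
    "overlap", class = "sietraj_data_error")

  # random frame vs exhaustive pairwise oracle, and rigid invariance
  cx <- make_toy_complex(seed = 12)
  top2 <- cx$topology; m <- cx$coords
  rec <- top2$groups$receptor; lig <- top2$groups$ligand
  heavy <- top2$atoms$element != "H"
  oracle <- sum(vapply(rec[heavy[rec]], function(i) {
    any(vapply(lig[heavy[lig]], function(j)
      sqrt(sum((m[i, ] - m[j, ])^2)) <= 3.5, logical(1)))
  }, logical(1)))
  expect_equal(atom_contacts(m, top2), oracle)
  moved <- m %*% random_rotation(31) + matrix(c(4, 4, 4), nrow(m), 3,
                                              byrow = TRUE)
  expect_equal(atom_contacts(moved, top2), oracle)
})

test_that("hydrogen-bond detection honours both criteria with inclusive bounds", {
  ok <- hb_system(2.8, 180)
  ev <- detect_hbonds(ok$coords, ok$top, "receptor", "ligand")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$distance_A, 2.8, tolerance = 1e-9)
  expect_equal(ev$angle_deg, 180, tolerance = 1e-9)

  too_far <- hb_system(3.6, 180)
  expect_equal(nrow(detect_hbonds(too_far$coords, too_far$top,
                                  "receptor", "ligand")), 0L)
  bent <- hb_system(2.8, 140)
  expect_equal(nrow(detect_hbonds(bent$coords, bent$top,
                                  "receptor", "ligand")), 0L)
  # boundaries inclusive: exactly 3.50 A and exactly 150.00 degrees pass
  at_dist <- hb_system(3.5, 180)
  expect_equal(nrow(detect_hbonds(at_dist$coords, at_dist$top,
                                  "receptor", "ligand")), 1L)
  at_angle <- hb_system(2.8, 150)
  ev2 <- detect_hbonds(at_angle$coords, at_angle$top, "receptor", "ligand")
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$angle_deg, 150, tolerance = 1e-6)

  nb <- hb_system()
  nb$top$bonds <- NULL
  expect_error(detect_hbonds(nb$coords, nb$top, "receptor", "ligand"),
               "bond", class = "sietraj_data_error")
})

test_that("detected bonds are a subset of the distance prefilter", {
  sc <- scripted_toy(n_frames = 40, seed = 5)
  top <- sc$tr$topology
  crit <- hbond_criteria()
  for (f in c(1, 20, 40)) {
    m <- sc$tr$coords[f, , ]
    ev <- detect_hbonds(m, top, "receptor", "ligand", crit)
    if (nrow(ev))
      expect_true(all(ev$distance_A <= crit$max_da_distance))
    # rigid invariance of the event set
    moved <- m %*% random_rotation(f) + 5
    ev2 <- detect_hbonds(moved, top, "receptor", "ligand", crit)
    expect_equal(ev2[, 1:3], ev[, 1:3])
  }
})

test_that("hbond occupancy counts window frames exactly and recovers targets", {
  # deterministic: bond engaged in exactly 40 of 100 frames
  hb <- hb_system(2.8, 180)
  arr <- array(NA_real_, c(100, 3, 3))
  far <- hb$coords; far[3, ] <- c(10, 0, 0)
  for (f in 1:100) arr[f, , ] <- if (f <= 40) hb$coords else far
  tr <- trajectory(hb$top, arr)
  expect_equal(hbond_occupancy(tr, donor = 1, acceptor = 3), 40.0)
  expect_equal(hbond_occupancy(tr, donor = 1, acceptor = 3,
                               window = 41:100), 0.0)
  # additivity over disjoint windows (weighted by window length)
  o1 <- hbond_occupancy(tr, 1, 3, window = 1:50)
  o2 <- hbond_occupancy(tr, 1, 3, window = 51:100)
  expect_equal((o1 * 50 + o2 * 50) / 100,
               hbond_occupancy(tr, 1, 3))
  expect_error(hbond_occupancy(tr, 1, 3, window = integer()),
               "window", class = "sietraj_data_error")

  # scripted occupancies recovered within 3 points at 2000 frames
  sc <- scripted_toy(n_frames = 2000, occupancies = c(0.7, 0.4), seed = 1)
  p1 <- sc$meta$pairs[[1]]; p2 <- sc$meta$pairs[[2]]
  expect_equal(hbond_occupancy(sc$tr, p1$donor, p1$acceptor), 70,
               tolerance = 3 / 70)
  expect_equal(hbond_occupancy(sc$tr, p2$donor, p2$acceptor), 40,
               tolerance = 3 / 40)
})

test_that("interaction maps localise hydrogen bonds and hydrophobic contacts", {
  # permanently engaged serine donor -> that residue at 100%, others 0
  sc <- scripted_toy(n_frames = 60, occupancies = c(1, 0), seed = 2)
  im <- interaction_map(sc$tr, window = 1:60)
  donor_res <- sc$tr$topology$atoms$resno[sc$meta$pairs[[1]]$donor]
  expect_equal(im$hbond_pct[im$resno == donor_res], 100)
  expect_equal(max(im$hbond_pct[im$resno != donor_res]), 0)
  expect_true(all(im$hydrophobic_pct[im$resno %in% sc$meta$pocket_residues] >
                    95))
  # scripted occupancies recovered in the map
  sc2 <- scripted_toy(n_frames = 1500, occupancies = c(0.65, 0.35), seed = 6)
  im2 <- interaction_map(sc2$tr)
  d1 <- sc2$tr$topology$atoms$resno[sc2$meta$pairs[[1]]$donor]
  a2 <- sc2$tr$topology$atoms$resno[sc2$meta$pairs[[2]]$acceptor]
  expect_equal(im2$hbond_pct[im2$resno == d1], 65, tolerance = 3 / 65)
  expect_equal(im2$hbond_pct[im2$resno == a2], 35, tolerance = 3 / 35)
})

test_that("an apolar pocket yields hydrophobic but no hydrogen-bond signal", {
  at <- data.frame(serial = 1:3, name = c("CB", "CB", "C1"),
                   element = "C", resname = c("LEU", "LEU", "LIG"),
                   resno = c(1L, 2L, 3L), chain = "A")
  top <- topology(at, bonds = rbind(c(1, 2)),
                  groups = list(receptor = 1:2, ligand = 3L))
  co <- rbind(c(3.0, 0, 0), c(0, 3.2, 0), c(0, 0, 0))
  arr <- array(NA_real_, c(2, 3, 3))
  arr[1, , ] <- co; arr[2, , ] <- co
  tr <- trajectory(top, arr)
  im <- interaction_map(tr)
  expect_equal(im$hbond_pct, c(0, 0))
  expect_equal(im$hydrophobic_pct, c(100, 100))
})

test_that("the analysis window defaults to the trajectory tail", {
  sc <- scripted_toy(n_frames = 200, seed = 9)
  w <- tail_window(sc$tr)
  expect_equal(w, 181:200)
  expect_equal(length(tail_window(sc$tr, 0.25)), 50)
  expect_error(tail_window(sc$tr, 0), class = "sietraj_config_error")
})
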