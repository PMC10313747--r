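test_that("Kabsch superposition recovers exact transforms", {
  set.seed(11)
  P <- matrix(rnorm(30), 10, 3)
  # identity
  f <- kabsch_superpose(P, P)
  expect_lt(f$rmsd, 1e-9)
  expect_lt(max(abs(f$rotation - diag(3))), 1e-9)
  # pure translation
  f <- kabsch_superpose(sweep(P, 2, c(-5, 3, -2)), P)
  expect_lt(f$rmsd, 1e-9)
  # known rotation + translation recovered
  R <- random_rotation(7)
  Q <- P %*% R + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  f <- kabsch_superpose(Q, P)
  expect_lt(f$rmsd, 1e-9)
  expect_lt(max(abs(f$rotation %*% R - diag(3))), 1e-9)
  expect_lt(max(abs(apply_superposition(Q, f) - P)), 1e-9)
  # proper rotation only
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "N >= 3", class = "sietraj_data_error")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear",
               class = "sietraj_data_error")
})

test_that("superposition agrees with the bio3d reference implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(rnorm(24), 8, 3)
    Q <- P %*% random_rotation(seed + 50) +
      matrix(rnorm(3), 8, 3, byrow = TRUE) + matrix(rnorm(24, 0, 0.3), 8, 3)
    ours <- kabsch_superpose(Q, P)$rmsd
    ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
    expect_equal(round(ours, 3), ref)  # bio3d reports 3 decimals
  }
})

test_that("RMSD series is zero for self, positive for deformation, exact on toys", {
  lt <- linear_topology(1:6)
  arr <- array(rep(lt$coords, each = 4), c(4, nrow(lt$coords), 3))
  tr <- trajectory(lt$top, arr)
  expect_equal(rmsd_series(tr)$rmsd_A, rep(0, 4))
  # uniform inflation about the centroid cannot be absorbed by a rigid fit
  infl <- sweep(sweep(lt$coords, 2, colMeans(lt$coords)) * 1.01, 2,
                colMeans(lt$coords), "+")
  expect_true(all(rmsd_series(tr, reference = infl)$rmsd_A > 0))
  # hand calculation: fit atoms identical, one measured atom displaced by d
  lt2 <- linear_topology(1:5)
  m2 <- lt2$coords
  m2[2, ] <- m2[2, ] + c(0, 0, 1.2)  # CB of residue 1
  arr2 <- array(NA_real_, c(2, nrow(m2), 3))
  arr2[1, , ] <- lt2$coords; arr2[2, , ] <- m2
  tr2 <- trajectory(lt2$top, arr2)
  out <- rmsd_series(tr2, fit_sel = selection("all", atoms = "CA"),
                     measure_sel = selection("1", atoms = "CB"))
  expect_equal(out$rmsd_A, c(0, sqrt(1.2^2 / 1)), tolerance = 1e-9)
})

test_that("RMSD is invariant under rigid transforms of either input", {
  lt <- linear_topology(1:6)
  base <- lt$coords
  set.seed(3)
  other <- base + matrix(rnorm(length(base), 0, 0.4), nrow(base), 3)
  r0 <- kabsch_superpose(other, base)$rmsd
  R <- random_rotation(21)
  moved <- other %*% R + matrix(c(3, -7, 2), nrow(base), 3, byrow = TRUE)
  expect_equal(kabsch_superpose(moved, base)$rmsd, r0, tolerance = 1e-9)
  expect_equal(kabsch_superpose(base, other)$rmsd, r0, tolerance = 1e-9)
})

test_that("RMSF is zero for static input and localises a mobile residue", {
  lt <- linear_topology(1:8)
  arr <- array(rep(lt$coords, each = 5), c(5, nrow(lt$coords), 3))
  tr <- trajectory(lt$top, arr)
  expect_equal(rmsf_per_residue(tr)$rmsf_A, rep(0, 8))
  expect_error(rmsf_per_residue(trajectory(lt$top, arr[1, , , drop = FALSE])),
               "2 frames", class = "sietraj_data_error")
  # jiggle only residue 5's CB; fit on CAs stays exact
  set.seed(8)
  cb5 <- which(lt$top$atoms$resno == 5 & lt$top$atoms$name == "CB")
  arr2 <- arr
  arr2[, cb5, ] <- arr2[, cb5, ] + matrix(rnorm(15, 0, 0.6), 5, 3)
  rf <- rmsf_per_residue(trajectory(lt$top, arr2),
                         sel = selection("all", atoms = "CB"))
  expect_true(rf$rmsf_A[rf$resno == 5] > 0.2)
  expect_equal(rf$rmsf_A[rf$resno != 5], rep(0, 7))
})

test_that("RMSF of isotropic jitter matches the sqrt(3)*sigma law", {
  cx <- make_toy_complex(seed = 1)
  tr <- simulate_gate_trajectory(
    cx, gate_params(n_frames = 5000, switch_prob = 0, start_state = "close",
                    jitter_sigma = 0.5, seed = 7))
  rf <- rmsf_per_residue(tr)
  expect_equal(mean(rf$rmsf_A), sqrt(3) * 0.5, tolerance = 0.03)
})

test_that("centroid distances are exact, symmetric, and basin-consistent", {
  at <- data.frame(serial = 1:2, name = "CA", element = "C",
                   resname = "ALA", resno = 1:2, chain = "A")
  top <- topology(at)
  arr <- array(NA_real_, c(1, 2, 3))
  arr[1, 1, ] <- c(0, 0, 0); arr[1, 2, ] <- c(0, 0, 19)
  tr <- trajectory(top, arr)
  d <- centroid_distance_series(tr, selection("1"), selection("2"))
  expect_equal(d$distance_A, 19)
  d2 <- centroid_distance_series(tr, selection("2"), selection("1"))
  expect_equal(d2$distance_A, d$distance_A)

  sc <- scripted_toy(n_frames = 400, seed = 3)
  ds <- centroid_distance_series(
    sc$tr, selection(sc$meta$loopA_range, atoms = "CA"),
    selection(sc$meta$loopB_range, atoms = "CA"))
  expect_gt(mean(ds$distance_A), 19)
  expect_lt(mean(ds$distance_A), 22)
})

test_that("conformation classification follows the open/close boundary", {
  th <- conformation_thresholds()
  expect_equal(classify_conformation(22.0, th), "open")
  expect_equal(classify_conformation(19.0, th), "close")
  expect_equal(classify_conformation(20.5, th), "open")  # tie -> open
  expect_equal(classify_conformation(c(18, 23), th), c("close", "open"))
  expect_error(conformation_thresholds(d_open = 19, d_close = 22),
               class = "sietraj_config_error")
})
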