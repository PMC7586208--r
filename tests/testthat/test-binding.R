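test_that("pairwise atom distances follow Euclidean geometry", {
  a <- toy_atoms(3)
  co <- array(0, c(3, 3, 1))
  co[2, , 1] <- c(0.3, 0.4, 0)       # 3-4-5 triangle, scaled
  co[3, , 1] <- c(0, 0, 0)
  traj <- newTrajectory(a, co)
  expect_equal(atomDistance(traj, 1, 1, 3), 0)
  expect_equal(atomDistance(traj, 1, 1, 2), 0.5)
  expect_error(atomDistance(traj, 1, 1, 9), "out of range")
})

test_that("site centre is the midpoint of the two pocket atoms", {
  a <- toy_atoms(2)
  co <- array(0, c(2, 3, 1)); co[2, , 1] <- c(1, 0, 0)
  traj <- newTrajectory(a, co)
  expect_equal(siteCenter(traj, 1, 1, 2), c(0.5, 0, 0))
  co[2, , 1] <- c(0, 0, 0)
  expect_equal(siteCenter(newTrajectory(a, co), 1, 1, 2), c(0, 0, 0))
  # random pairs against a component-wise mean oracle
  set.seed(7)
  for (i in 1:10) {
    co[1, , 1] <- rnorm(3); co[2, , 1] <- rnorm(3)
    traj <- newTrajectory(a, co)
    expect_equal(siteCenter(traj, 1, 1, 2),
                 (co[1, , 1] + co[2, , 1]) / 2)
  }
})

test_that("ligand centre of mass is the mass-weighted mean position", {
  a <- toy_atoms(2, mass = c(12, 16))
  co <- array(0, c(2, 3, 1)); co[2, 1, 1] <- 0.28
  traj <- newTrajectory(a, co)
  expect_equal(ligandCOM(traj, 1, 1:2)[1], 16 * 0.28 / 28)
  expect_equal(unname(ligandCOM(traj, 1, 1:2)), c(0.16, 0, 0))
  expect_equal(unname(ligandCOM(traj, 1, 1L)), c(0, 0, 0))  # single atom
  a2 <- toy_atoms(2, mass = c(5, 5))
  expect_equal(unname(ligandCOM(newTrajectory(a2, co), 1, 1:2)),
               c(0.14, 0, 0))                               # equal masses
  expect_error(ligandCOM(traj, 1, integer(0)), "empty")
})

test_that("pocket width tracks the generator's breathing exactly", {
  n <- 50
  times <- seq(0, 49, by = 1)
  w <- 1.0 + 0.2 * sin(2 * pi * times / 25)
  a <- toy_atoms(2, resseq = c(176L, 209L))
  co <- array(0, c(2, 3, n))
  co[1, 1, ] <- -w / 2; co[2, 1, ] <- w / 2
  traj <- newTrajectory(a, co, times)
  s <- pocketWidthSeries(traj, atomSelector(resseq = 176),
                         atomSelector(resseq = 209))
  expect_equal(seriesValues(s), w, tolerance = 1e-12)
  expect_length(s, n)

  # static trajectory gives a constant series
  co2 <- co; co2[1, 1, ] <- -0.4; co2[2, 1, ] <- 0.4
  s2 <- pocketWidthSeries(newTrajectory(a, co2, times),
                          atomSelector(resseq = 176),
                          atomSelector(resseq = 209))
  expect_true(all(seriesValues(s2) == 0.8))

  # ambiguous selector is rejected
  expect_error(pocketWidthSeries(traj, atomSelector(atom = "CA"),
                                 atomSelector(resseq = 209)),
               "exactly one")
})

test_that("engagement series equals a frame-by-frame recompute", {
  sim <- simulateTrajectory(nFrames = 301, dt = 0.5, seed = 5)
  traj <- sim$traj
  ligSel <- atomSelector(chain = "L")
  selA <- atomSelector(resseq = 176, atom = "CA")
  selB <- atomSelector(resseq = 209, atom = "CA")
  es <- engagementSeries(traj, ligSel, selA, selB)
  # oracle: per-frame COM and midpoint recomputed through the frame ops
  lig <- selectAtoms(traj, ligSel)
  lig <- lig[atoms(traj)$element[lig] != "H"]
  ia <- selectAtoms(traj, selA); ib <- selectAtoms(traj, selB)
  want <- vapply(seq_len(nFrames(traj)), function(k) {
    com <- ligandCOM(traj, k, lig)
    ctr <- siteCenter(traj, k, ia, ib)
    sqrt(sum((com - ctr)^2))
  }, numeric(1))
  expect_equal(seriesValues(es), want, tolerance = 1e-12)
  # and equals the generator's emitted ground truth
  expect_equal(seriesValues(es), sim$truth$engagement, tolerance = 1e-9)

  expect_error(engagementSeries(traj, atomSelector(chain = "Q"),
                                selA, selB), "no atoms")
})

test_that("ligand pinned at the site centre gives an all-zero series", {
  a <- rbind(toy_atoms(2, resseq = c(176L, 209L)),
             data.frame(serial = 3L, name = "C1", element = "C",
                        resname = "LIG", resseq = 1L, chain = "L",
                        mass = 300))
  n <- 10
  co <- array(0, c(3, 3, n))
  co[1, 1, ] <- -seq(0.4, 0.6, length.out = n)
  co[2, 1, ] <- seq(0.4, 0.6, length.out = n)
  traj <- newTrajectory(a, co, times = seq_len(n))
  es <- engagementSeries(traj, atomSelector(chain = "L"),
                         atomSelector(resseq = 176),
                         atomSelector(resseq = 209))
  expect_true(all(seriesValues(es) == 0))
})

test_that("bound-interval classification matches the run-length oracle", {
  # injected runs of 2, 7 and 30 ns at 1 ns spacing, min dwell 5 ns
  times <- 0:59
  v <- rep(1.5, 60)
  v[3:5] <- 0.5     # 2 ns run (times 2..4)
  v[10:17] <- 0.5   # 7 ns run (times 9..16)
  v[25:55] <- 0.5   # 30 ns run
  bi <- classifyBound(distanceSeries(times, v, ""), cutoff = 0.8, minDwell = 5)
  expect_equal(nrow(intervals(bi)), 2)
  expect_equal(unname(intervals(bi)[, "end"] - intervals(bi)[, "start"]),
               c(7, 30))

  # all below / all above
  all_in <- classifyBound(distanceSeries(times, rep(0.1, 60), ""), 0.8, 5)
  expect_equal(unname(intervals(all_in)[1, ]), c(0, 59))
  all_out <- classifyBound(distanceSeries(times, rep(2, 60), ""), 0.8, 5)
  expect_equal(nrow(intervals(all_out)), 0)

  # random series vs independent run scan
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:120, 1)
    tt <- cumsum(runif(n, 0.5, 2))
    vv <- runif(n, 0, 1.6)
    md <- runif(1, 0, 6)
    got <- intervals(classifyBound(distanceSeries(tt, vv, ""), 0.8, md))
    want <- runscan_intervals(tt, vv, 0.8, md)
    expect_equal(unname(got), unname(want))
  }
})

test_that("H-bond series respects the measurement mode", {
  # donor 0.3 nm from acceptor, hydrogen 0.2 nm from acceptor
  a <- rbind(toy_atoms(1, name = "OD1", element = "O", resseq = 172L),
             data.frame(serial = 2:3, name = c("N1", "H1"),
                        element = c("N", "H"), resname = "LIG",
                        resseq = 1L, chain = "L", mass = c(14, 1)))
  n <- 5
  co <- array(0, c(3, 3, n))
  co[2, 2, ] <- 0.3
  co[3, 2, ] <- 0.2
  traj <- newTrajectory(a, co, seq_len(n))
  specH <- hbondSpec(donor = atomSelector(atom = "N1"),
                     acceptor = atomSelector(atom = "OD1"),
                     hydrogen = atomSelector(atom = "H1"))
  specN <- hbondSpec(donor = atomSelector(atom = "N1"),
                     acceptor = atomSelector(atom = "OD1"))
  expect_equal(specH@cutoff, 0.25)   # default criteria per mode
  expect_equal(specN@cutoff, 0.36)
  expect_true(all(seriesValues(hbondSeries(traj, specH)) == 0.2))
  expect_true(all(seriesValues(hbondSeries(traj, specN)) == 0.3))
  expect_error(hbondSpec(donor = atomSelector(atom = "N1"),
                         acceptor = atomSelector(atom = "OD1"),
                         mode = "H_TO_ACCEPTOR"), "hydrogen")

  # synthetic bond-forming trajectory matches the generator's distances
  sim <- simulateTrajectory(nFrames = 301, dt = 0.5, seed = 5)
  hs <- hbondSeries(sim$traj,
                    hbondSpec(donor = atomSelector(atom = "N1"),
                              acceptor = atomSelector(atom = "OD1"),
                              hydrogen = atomSelector(atom = "H1")))
  expect_equal(seriesValues(hs), sim$truth$hbond, tolerance = 1e-9)
})

test_that("occupancy is the time-weighted fraction under the criterion", {
  s_low <- distanceSeries(1:10, rep(0.2, 10), "")
  s_high <- distanceSeries(1:10, rep(0.4, 10), "")
  expect_equal(hbondOccupancy(s_low, 0.25), 1)
  expect_equal(hbondOccupancy(s_high, 0.25), 0)

  # uneven spacing against the explicit interval-sum oracle
  set.seed(3)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    tt <- cumsum(runif(n, 0.1, 3))
    vv <- runif(n, 0, 0.5)
    expect_equal(hbondOccupancy(distanceSeries(tt, vv, ""), 0.25),
                 intervalsum_occupancy(tt, vv, 0.25))
  }

  # monotone non-decreasing in the cutoff; limits 0 and 1
  tt <- cumsum(runif(30, 0.1, 2)); vv <- runif(30, 0, 0.6)
  s <- distanceSeries(tt, vv, "")
  cuts <- seq(0.01, 0.7, by = 0.01)
  occ <- vapply(cuts, function(ct) hbondOccupancy(s, ct), numeric(1))
  expect_true(all(diff(occ) >= 0))
  expect_equal(hbondOccupancy(s, 1e6), 1)
  expect_equal(hbondOccupancy(s, 1e-9), 0)
})

test_that("snapshot selection picks the widest pocket, earliest on ties", {
  a <- toy_atoms(2, resseq = c(176L, 209L))
  n <- 30
  selA <- atomSelector(resseq = 176); selB <- atomSelector(resseq = 209)
  # strictly increasing widths -> last frame
  co <- array(0, c(2, 3, n)); co[2, 1, ] <- seq(0.8, 1.2, length.out = n)
  expect_equal(selectMaxWidthFrame(newTrajectory(a, co, 1:n), selA, selB), n)
  # constant widths -> first frame
  co[2, 1, ] <- 1
  expect_equal(selectMaxWidthFrame(newTrajectory(a, co, 1:n), selA, selB), 1)
  # random widths -> linear-scan argmax oracle
  set.seed(21)
  for (i in 1:10) {
    w <- runif(n, 0.8, 1.2)
    co[2, 1, ] <- w
    got <- selectMaxWidthFrame(newTrajectory(a, co, 1:n), selA, selB)
    expect_equal(got, which(w == max(w))[1])
  }
})

test_that("geometric series are invariant under global rigid motion", {
  sim <- simulateTrajectory(nFrames = 101, dt = 0.5, seed = 13)
  traj <- sim$traj
  set.seed(31)
  moved <- transform_trajectory(traj, random_rotation(), rnorm(3, 0, 5))
  selA <- atomSelector(resseq = 176, atom = "CA")
  selB <- atomSelector(resseq = 209, atom = "CA")
  expect_equal(seriesValues(pocketWidthSeries(moved, selA, selB)),
               seriesValues(pocketWidthSeries(traj, selA, selB)),
               tolerance = 1e-9)
  expect_equal(
    seriesValues(engagementSeries(moved, atomSelector(chain = "L"),
                                  selA, selB)),
    seriesValues(engagementSeries(traj, atomSelector(chain = "L"),
                                  selA, selB)),
    tolerance = 1e-9)
})

test_that("superposition RMSD implements the least-squares Kabsch contract", {
  set.seed(8)
  A <- matrix(rnorm(36), 12)
  # identical sets superpose to zero
  expect_equal(superposeRMSD(A, A), 0)
  # a rigidly moved copy superposes to zero
  moved <- A %*% t(random_rotation()) +
    matrix(c(3, -2, 7), nrow(A), 3, byrow = TRUE)
  expect_lt(superposeRMSD(A, moved), 1e-6)
  # symmetry and the upper bound by the unsuperposed deviation
  B <- A + matrix(rnorm(36, 0, 0.3), 12)
  expect_equal(superposeRMSD(A, B), superposeRMSD(B, A), tolerance = 1e-6)
  raw <- sqrt(mean(rowSums((A - B)^2))) * 10
  expect_lte(superposeRMSD(A, B), raw + 1e-9)
  # error contracts
  expect_error(superposeRMSD(A, A[1:5, ]), "identical dimensions")
  expect_error(superposeRMSD(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("superposition matches a numerical-minimization oracle on toys", {
  set.seed(17)
  for (i in 1:6) {
    ref <- matrix(rnorm(12), 4)
    mob <- ref
    mob[1, ] <- mob[1, ] + rnorm(3, 0, 0.4)    # one displaced point
    mob <- mob %*% t(random_rotation()) +
      matrix(rnorm(3), 4, 3, byrow = TRUE)
    expect_equal(superposeRMSD(ref, mob), bruteforce_rmsd(ref, mob),
                 tolerance = 1e-4)
  }
})
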