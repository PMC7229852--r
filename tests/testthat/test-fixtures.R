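test_that("generators are deterministic: same spec and seed, identical files", {
  d1 <- withr::local_tempdir()
  sc1 <- makeDuplexScene("ATATAGCGCATATA", jitter = 0.05, nFrames = 3, seed = 42)
  sc2 <- makeDuplexScene("ATATAGCGCATATA", jitter = 0.05, nFrames = 3, seed = 42)
  f1 <- file.path(d1, "a.dat"); f2 <- file.path(d1, "b.dat")
  writeOxTrajectory(sc1$trajectory, f1)
  writeOxTrajectory(sc2$trajectory, f2)
  expect_identical(readLines(f1), readLines(f2))
  p1 <- makeProbeCloud(2, 100, seed = 9)
  p2 <- makeProbeCloud(2, 100, seed = 9)
  expect_identical(positions(p1), positions(p2))
  t1 <- makeTwoStateTrajectory(matrix(1:30, 10, 3), nFrames = 50, seed = 3)
  t2 <- makeTwoStateTrajectory(matrix(1:30, 10, 3), nFrames = 50, seed = 3)
  expect_identical(t1$truth$a, t2$truth$a)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(makeDuplexScene("ATATAGCGCATATA", jitter = 0.1, nFrames = 2, seed = 7))
  expect_identical(rnorm(3), before)
})

test_that("zero-jitter duplex frames are identical; jittered RMSF is sigma*sqrt(3)", {
  sc <- makeDuplexScene("ATATAGCGCATATA", jitter = 0, nFrames = 3, seed = 0)
  expect_identical(positions(sc$trajectory)[, , 1], positions(sc$trajectory)[, , 3])
  expect_error(makeDuplexScene("ATATAGCGCATATA", jitter = -1), "jitter")
  expect_error(makeDuplexScene("GCGC"), ">= 10")
  ## closed form: sqrt(E|r - mu|^2) = sigma * sqrt(3) per nucleotide
  scj <- makeDuplexScene(strrep("AT", 7), jitter = 0.05, nFrames = 1000, seed = 1)
  aa <- alignAndAverage(scj$trajectory, seq_len(28))
  expect_equal(mean(aa$rmsf), 0.05 * sqrt(3), tolerance = 0.05)
})

test_that("raft gap schedules are honoured exactly", {
  gaps <- c(0.5, 10, 2.5)
  sc <- makeRaftScene(nHelices = 3, gapSchedule = gaps, seed = 0)
  n <- 14
  for (t in seq_along(gaps)) {
    up <- positions(sc$trajectory)[2 * n + seq_len(2 * n), , t]
    expect_equal(mean(up[, 2]), -(gaps[t] + 1.2), tolerance = 1e-9)
  }
  expect_error(makeRaftScene(nHelices = 1, gapSchedule = 1), "at least 2")
  expect_error(makeRaftScene(gapSchedule = -1), ">= 0")
  ## analytic labels: clear iff gap above probeExtent - 0.4
  expect_identical(sc$truth$labels, gaps > sc$truth$threshold)
})

test_that("raft files round-trip through the oxDNA readers", {
  sc <- makeRaftScene(nHelices = 3, gapSchedule = c(1, 5), seed = 0)
  d <- withr::local_tempdir()
  writeOxTopology(sc$topology, file.path(d, "r.top"))
  writeOxTrajectory(sc$trajectory, file.path(d, "r.dat"))
  top <- readOxTopology(file.path(d, "r.top"))
  traj <- readOxTrajectory(file.path(d, "r.dat"), top)
  expect_identical(nFrames(traj), 2L)
  expect_lt(max(abs(positions(traj) - positions(sc$trajectory))), 1e-6)
  ## geometric pairing on the read-back scene recovers the construction
  top2 <- inferPairing(top, getFrame(traj, 1))
  expect_identical(top2@pairing, sc$topology@pairing)
})

test_that("two-state generator obeys its Boltzmann statistics", {
  base <- matrix(seq_len(18), 6, 3)
  ts <- makeTwoStateTrajectory(base, barrier = 3, minima = c(-2, 2),
                               nFrames = 50000, seed = 0)
  a <- ts$truth$a
  ## symmetric wells: populations 0.5 within 3 SE, with the effective sample
  ## size taken as the number of well-to-well transitions
  lab <- a > 0
  nTrans <- sum(diff(lab) != 0)
  se <- 0.5 / sqrt(nTrans)
  expect_gt(nTrans, 50)
  expect_lt(abs(mean(lab) - 0.5), 3 * se)
  ## occupancy ratio matches the numerically integrated Boltzmann weights of
  ## the planted potential in a tilted variant
  tst <- makeTwoStateTrajectory(base, barrier = 3, minima = c(-2, 2),
                                tilt = 1.5, nFrames = 50000, seed = 1)
  U <- tst$truth$potential
  zLeft <- integrate(function(s) exp(-U(s)), -Inf, 0)$value
  zRight <- integrate(function(s) exp(-U(s)), 0, Inf)$value
  labT <- tst$truth$a > 0
  nT <- max(sum(diff(labT) != 0), 1)
  pRight <- zRight / (zLeft + zRight)
  expect_lt(abs(mean(labT) - pRight), 3 * sqrt(pRight * (1 - pRight) / nT) + 0.02)
})

test_that("zero-noise two-state frames lie exactly on the planted line", {
  base <- matrix(seq_len(30), 10, 3)
  ts <- makeTwoStateTrajectory(base, nFrames = 100, seed = 2, noise = 0)
  modeMat <- matrix(ts$truth$mode, 10, 3, byrow = TRUE)
  for (t in c(1, 50, 100)) {
    dev <- positions(ts$trajectory)[, , t] - base
    expect_equal(dev, ts$truth$a[t] * modeMat, tolerance = 1e-9)
  }
  expect_error(makeTwoStateTrajectory(base, mode = rep(1, 30)), "unit norm")
  expect_error(makeTwoStateTrajectory(base, barrier = -1), "barrier")
})

test_that("probe clouds fill the stated ball", {
  p <- makeProbeCloud(1, 10000, offset = 0, seed = 0, axialCenter = 0)
  r <- sqrt(rowSums(positions(p)^2))
  expect_lte(max(r), 1)
  expect_gte(max(r), 0.99)
  single <- makeProbeCloud(1e-9, 1, offset = 2, seed = 0, axialCenter = 0)
  expect_equal(positions(single)[1, ], c(2, 0, 0), tolerance = 1e-8)
  expect_error(makeProbeCloud(0, 10), "extent")
  expect_error(makeProbeCloud(1, 0), "particle")
})
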