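rigidlyJiggledTrajectory <- function(base, nFrames, seed = 0) {
  ## identical structure under a random rigid motion per frame
  set.seed(seed)
  N <- nrow(base)
  pos <- array(0, c(N, 3, nFrames))
  for (t in seq_len(nFrames))
    pos[, , t] <- sweep(base %*% t(randomRotation()), 2, rnorm(3, sd = 5), "+")
  top <- new("OxTopology", nNucleotides = N, nStrands = 1L,
             strandId = rep(1L, N), base = rep("A", N),
             neighbor3 = c(2:N, NA), neighbor5 = c(NA, 1:(N - 1)),
             pairing = integer(0), circular = FALSE)
  new("OxTrajectory", topology = top, positions = pos,
      bbVersors = array(rep(c(1, 0, 0), each = N), c(N, 3, nFrames)),
      normVersors = array(rep(c(0, 0, 1), each = N), c(N, 3, nFrames)),
      times = seq_len(nFrames), boxes = matrix(100, 3, nFrames),
      lengthUnit = 0.8518)
}

test_that("rigid motions alone leave zero RMSF after alignment", {
  set.seed(1)
  base <- matrix(rnorm(45), 15, 3)
  traj <- rigidlyJiggledTrajectory(base, 20)
  aa <- alignAndAverage(traj, 1:15)
  expect_lt(max(aa$rmsf), 1e-9)
  expect_lt(max(abs(aa$mean - positions(aa$aligned)[, , 1])), 1e-9)
})

test_that("isotropic jitter gives RMSF = sigma * sqrt(3)", {
  sc <- makeDuplexScene(strrep("ACGT", 5), jitter = 0.05, nFrames = 1000, seed = 4)
  aa <- alignAndAverage(sc$trajectory, seq_len(nNucleotides(sc$trajectory)))
  expect_equal(mean(aa$rmsf), 0.05 * sqrt(3), tolerance = 0.05)
})

test_that("a two-frame single-particle displacement gives rmsf d/2", {
  set.seed(2)
  base <- matrix(rnorm(60), 20, 3)
  pos <- array(base, c(20, 3, 2))
  pos[20, 1, 2] <- pos[20, 1, 2] + 0.8
  top <- new("OxTopology", nNucleotides = 20L, nStrands = 1L,
             strandId = rep(1L, 20), base = rep("A", 20),
             neighbor3 = c(2:20, NA), neighbor5 = c(NA, 1:19),
             pairing = integer(0), circular = FALSE)
  traj <- new("OxTrajectory", topology = top, positions = pos,
              bbVersors = array(rep(c(1, 0, 0), each = 20), c(20, 3, 2)),
              normVersors = array(rep(c(0, 0, 1), each = 20), c(20, 3, 2)),
              times = 1:2, boxes = matrix(100, 3, 2), lengthUnit = 0.8518)
  ## align on the unmoved particles so the displacement stays put
  aa <- alignAndAverage(traj, 1:19)
  expect_lt(max(aa$rmsf[1:19]), 1e-9)
  rmsfAll <- sqrt(apply((traj@positions[, , 1:2] -
                           array(apply(traj@positions, c(1, 2), mean),
                                 c(20, 3, 2)))^2, 1, sum) / 2)
  expect_equal(rmsfAll[20], 0.8 / 2, tolerance = 1e-9)
})

test_that("a planted rank-1 fluctuation is recovered exactly", {
  set.seed(3)
  N <- 12
  base <- matrix(rnorm(3 * N), N, 3)
  v <- rnorm(3 * N); v <- v / sqrt(sum(v^2))
  a <- rnorm(50, sd = 0.7)
  pos <- array(0, c(N, 3, 50))
  for (t in 1:50) pos[, , t] <- base + a[t] * matrix(v, N, 3, byrow = TRUE)
  ## build without alignment: frames differ only along v
  top <- new("OxTopology", nNucleotides = as.integer(N), nStrands = 1L,
             strandId = rep(1L, N), base = rep("A", N),
             neighbor3 = c(2:N, NA), neighbor5 = c(NA, 1:(N - 1)),
             pairing = integer(0), circular = FALSE)
  traj <- new("OxTrajectory", topology = top, positions = pos,
              bbVersors = array(rep(c(1, 0, 0), each = N), c(N, 3, 50)),
              normVersors = array(rep(c(0, 0, 1), each = N), c(N, 3, 50)),
              times = 1:50, boxes = matrix(100, 3, 50), lengthUnit = 0.8518)
  sp <- covarianceModes(traj, seq_len(N))
  sVar <- mean((a - mean(a))^2)          # population variance, as in C = (1/T) sum
  expect_equal(eigenvalues(sp)[1], sVar, tolerance = 1e-8)
  expect_equal(abs(sum(eigenvectors(sp)[, 1] * v)), 1, tolerance = 1e-8)
  expect_lt(eigenvalues(sp)[2], 1e-10)
  expect_equal(totalMsf(sp), sum(eigenvalues(sp)))
})

test_that("spectra match a brute-force covariance assembly oracle", {
  sc <- makeDuplexScene(strrep("GATC", 3), jitter = 0.08, nFrames = 200, seed = 5)
  N <- nNucleotides(sc$trajectory)
  aa <- alignAndAverage(sc$trajectory, seq_len(N))
  sp <- covarianceModes(aa$aligned, seq_len(N))
  ## oracle: assemble C element-wise from explicit deviation vectors
  X <- t(vapply(seq_len(200), function(t)
    as.vector(t(positions(aa$aligned)[, , t])), numeric(3 * N)))
  X <- sweep(X, 2, colMeans(X))
  C <- matrix(0, 3 * N, 3 * N)
  for (t in 1:200) C <- C + outer(X[t, ], X[t, ])
  C <- C / 200
  e <- eigen(C, symmetric = TRUE)
  expect_equal(eigenvalues(sp), pmax(e$values, 0), tolerance = 1e-8)
  for (j in 1:5)
    expect_equal(abs(sum(eigenvectors(sp)[, j] * e$vectors[, j])), 1,
                 tolerance = 1e-8)
})

test_that("Parseval holds for the full spectrum", {
  sc <- makeDuplexScene(strrep("GATC", 3), jitter = 0.05, nFrames = 80, seed = 6)
  N <- nNucleotides(sc$trajectory)
  aa <- alignAndAverage(sc$trajectory, seq_len(N))
  sp <- covarianceModes(aa$aligned, seq_len(N))
  x <- as.vector(t(positions(aa$aligned)[, , 17])) - meanStructure(sp)
  expect_equal(sum(crossprod(eigenvectors(sp), x)^2), sum(x^2),
               tolerance = 1e-6 * sum(x^2))
  ## total MSF equals the mean squared deviation summed over the selection
  msd <- mean(vapply(seq_len(80), function(t)
    sum((as.vector(t(positions(aa$aligned)[, , t])) - meanStructure(sp))^2),
    numeric(1)))
  expect_equal(totalMsf(sp), msd, tolerance = 1e-6 * msd)
})

test_that("collinearity of a spectrum with itself is the identity", {
  sc <- makeDuplexScene(strrep("GATC", 3), jitter = 0.05, nFrames = 60, seed = 7)
  N <- nNucleotides(sc$trajectory)
  aa <- alignAndAverage(sc$trajectory, seq_len(N))
  sp <- covarianceModes(aa$aligned, seq_len(N))
  M <- collinearityMatrix(sp, sp, k = 10)
  expect_lt(max(abs(M - diag(10))), 1e-8)
})

test_that("a swap of modes 4 and 5 shows as a permutation pattern", {
  sc <- makeDuplexScene(strrep("GATC", 3), jitter = 0.05, nFrames = 60, seed = 8)
  N <- nNucleotides(sc$trajectory)
  aa <- alignAndAverage(sc$trajectory, seq_len(N))
  spA <- covarianceModes(aa$aligned, seq_len(N))
  spB <- spA
  spB@eigenvectors[, c(4, 5)] <- spB@eigenvectors[, c(5, 4)]
  spB@eigenvalues[c(4, 5)] <- spB@eigenvalues[c(5, 4)]
  M <- collinearityMatrix(spA, spB, k = 6)
  expected <- diag(6)
  expected[4, 4] <- expected[5, 5] <- 0
  expected[4, 5] <- expected[5, 4] <- 1
  expect_lt(max(abs(M - expected)), 1e-8)
})

test_that("off-diagonal collinearity of independent spectra matches random-vector overlap", {
  set.seed(9)
  sc1 <- makeDuplexScene(strrep("GATC", 8), jitter = 0.05, nFrames = 80, seed = 10)
  sc2 <- makeDuplexScene(strrep("GATC", 8), jitter = 0.05, nFrames = 80, seed = 11)
  N <- nNucleotides(sc1$trajectory)
  spA <- covarianceModes(alignAndAverage(sc1$trajectory, 1:N)$aligned, 1:N)
  spB <- covarianceModes(alignAndAverage(sc2$trajectory, 1:N)$aligned, 1:N)
  M <- collinearityMatrix(spA, spB, k = 10)
  off <- mean(M[row(M) != col(M)])
  ## sampling oracle: mean |<u,v>| for random unit vectors in R^(3N)
  d <- 3 * N
  sim <- replicate(2000, {
    u <- rnorm(d); v <- rnorm(d)
    abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  })
  ## three standard errors of the 90 off-diagonal entries
  expect_lt(abs(off - mean(sim)), 3 * sd(sim) / sqrt(90) + 3 * sd(sim) / sqrt(2000))
})

test_that("projections recover planted displacements", {
  set.seed(12)
  base <- matrix(rnorm(60), 20, 3) * 3
  ts <- makeTwoStateTrajectory(base, barrier = 3, minima = c(-2, 2),
                               noise = 0.2, nFrames = 2000, seed = 1)
  aa <- alignAndAverage(ts$trajectory, 1:20)
  sp <- covarianceModes(aa$aligned, 1:20)
  pr <- projectOntoMode(aa$aligned, sp, mode = 1)
  expect_gt(abs(cor(values(pr), ts$truth$a)), 0.99)
  ## frame equal to the centre projects to 0; centre + 2.5 * mode to 2.5
  traj1 <- aa$aligned
  traj1@positions[1:20, , 1] <- matrix(meanStructure(sp), 20, 3, byrow = TRUE)
  traj1@positions[1:20, , 2] <- matrix(meanStructure(sp) +
                                         2.5 * eigenvectors(sp)[, 1],
                                       20, 3, byrow = TRUE)
  pr1 <- projectOntoMode(traj1, sp, mode = 1)
  expect_equal(values(pr1)[1], 0, tolerance = 1e-9)
  expect_equal(values(pr1)[2], 2.5, tolerance = 1e-9)
  ## series from the same spectrum is mean-centred
  expect_lt(abs(mean(values(pr))), 1e-6 * sd(values(pr)))
})

test_that("cross-structure projection demands an explicit index mapping", {
  sc <- makeDuplexScene(strrep("GATC", 3), jitter = 0.05, nFrames = 30, seed = 13)
  N <- nNucleotides(sc$trajectory)
  aa <- alignAndAverage(sc$trajectory, 1:12)
  sp <- covarianceModes(aa$aligned, 1:12)
  expect_error(projectOntoMode(aa$aligned, sp, 1, indexMap = 1:5), "mapping")
  ## a shifted mapping projects the mapped coordinates
  pr <- projectOntoMode(aa$aligned, sp, 1, indexMap = 13:24)
  expect_length(values(pr), 30)
})
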