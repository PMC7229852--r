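test_that("docking templates preserve probe geometry and are pose-invariant", {
  helix <- buildIdealHelix(10)
  probe <- makeProbeCloud(1.5, 500, offset = 2, seed = 1)
  ## synthetic "crystal": the helix anchors themselves as a two-chain duplex
  anchors <- helixAnchors(helix)
  crystal <- new("ParticleCloud", positions = anchors,
                 labels = data.frame(chain = rep(c("A", "B"), each = 10),
                                     resid = c(1:10, 10:1), atom = "P"),
                 role = "dna")
  tmplA <- buildDockingTemplate(probe, crystal, helix)
  expect_lt(tmplA@rmsd, 1e-9)
  expect_lt(max(abs(positions(tmplA@protein) - positions(probe))), 1e-9)
  ## pre-rotated crystal+probe give the identical template (relative geometry)
  set.seed(2)
  tf <- rigidTransform(randomRotation(), c(4, -1, 2))
  tmplB <- buildDockingTemplate(applyTransform(tf, probe),
                                applyTransform(tf, crystal), helix)
  expect_lt(max(abs(positions(tmplB@protein) - positions(tmplA@protein))), 1e-9)
  ## maximal radial extent of an offset ball: offset + radius
  wide <- makeProbeCloud(1.5, 20000, offset = 2, seed = 3)
  tmplC <- probeTemplate(wide, helix)
  rad <- sqrt(rowSums(positions(tmplC@protein)[, 1:2]^2))
  expect_lte(max(rad), 3.5 + 1e-9)
  expect_gt(max(rad), 3.5 - 0.05)
})

test_that("docking onto the verbatim helix reproduces the template pose", {
  sc <- makeDuplexScene("ATATAGCGCATATA", seed = 0)
  site <- sceneSite(sc)
  cfg <- getFrame(sc$trajectory, 1)
  tmpl <- probeTemplate(makeProbeCloud(1, 100, offset = 2, seed = 4))
  d <- dockToSite(tmpl, cfg, site, "scaffold")
  expect_lt(d$rmsd, 1e-9)
  ## window starts at bp 3: template moves up by 2 bp of rise and twist
  phi <- 2 * (360 / 10.5) * pi / 180
  Rz <- matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  expected <- sweep(positions(tmpl@protein) %*% t(Rz), 2, c(0, 0, 2 * 0.34), "+")
  expect_lt(max(abs(positions(d$protein) - expected)), 1e-9)
})

test_that("docking is equivariant under rigid motions of the frame", {
  sc <- makeDuplexScene("ATATAGCGCATATA", jitter = 0.02, seed = 5)
  site <- sceneSite(sc)
  cfg <- getFrame(sc$trajectory, 1)
  tmpl <- probeTemplate(makeProbeCloud(1, 100, offset = 2, seed = 6))
  d0 <- dockToSite(tmpl, cfg, site, "scaffold")
  set.seed(7)
  R <- randomRotation(); tr <- c(-3, 8, 1)
  cfg2 <- cfg
  cfg2@positions <- sweep(cfg@positions %*% t(R), 2, tr, "+")
  cfg2@bbVersor <- cfg@bbVersor %*% t(R)
  cfg2@normVersor <- cfg@normVersor %*% t(R)
  d1 <- dockToSite(tmpl, cfg2, site, "staple")
  d0s <- dockToSite(tmpl, cfg, site, "staple")
  expect_lt(max(abs(positions(d1$protein) -
                      sweep(positions(d0s$protein) %*% t(R), 2, tr, "+"))), 1e-9)
})

test_that("the staple side is the pseudo-dyad flip of the scaffold side", {
  sc <- makeDuplexScene("ATTGCGCGCAATAT", seed = 0)  # window is palindomic-ready
  site <- sceneSite(sc)
  cfg <- getFrame(sc$trajectory, 1)
  tmpl <- probeTemplate(makeProbeCloud(1.2, 300, offset = 2.2, seed = 8))
  dS <- dockToSite(tmpl, cfg, site, "scaffold")
  dP <- dockToSite(tmpl, cfg, site, "staple")
  ## explicit flip-matrix oracle: 180 degrees about the window dyad axis.
  ## window = bp 3..12, twist t: dyad azimuth ((w1 + w10 - 2) * t + 180) / 2
  tw <- 360 / 10.5
  alpha <- ((2 + 11) * tw + 180) / 2 * pi / 180
  u <- c(cos(alpha), sin(alpha), 0)
  M <- 2 * outer(u, u) - diag(3)
  mid <- c(0, 0, (2 + 11) / 2 * 0.34)
  flipped <- sweep(sweep(positions(dS$protein), 2, mid) %*% t(M), 2, mid, "+")
  expect_lt(max(abs(positions(dP$protein) - flipped)), 1e-9)
})

test_that("distance maps place single particles in the correct cell", {
  sc <- makeDuplexScene("ATATAGCGCATATA", seed = 0)
  site <- sceneSite(sc)
  cfg <- getFrame(sc$trajectory, 1)
  frame <- estimateSiteFrame(cfg, cbind(site@windowScaffoldIdx,
                                        site@windowStapleIdx), 6L)
  bpC <- (cfg@positions[site@windowScaffoldIdx, ] +
            cfg@positions[site@windowStapleIdx, ]) / 2
  ## environment particle beside bp 5 at azimuth 30 degrees, distance 1.2 nm
  th <- 30 * pi / 180
  pt <- bpC[5, ] + 1.2 * (cos(th) * frame@ref + sin(th) * frame@third)
  protein <- matrix(bpC[5, ] + 0.3 * frame@ref, 1, 3)
  maps <- distanceMaps(protein, frame, bpC, matrix(pt, 1, 3), nTheta = 72)
  finite <- which(is.finite(maps@minMap), arr.ind = TRUE)
  expect_identical(nrow(finite), 1L)
  expect_identical(unname(finite[1, "row"]), 5L)
  expect_identical(unname(finite[1, "col"]), findInterval(th, maps@thetaBreaks))
  expect_equal(maps@minMap[finite], 1.2, tolerance = 1e-9)
  ## no environment: min map all +Inf and the scene is accessible
  maps0 <- distanceMaps(protein, frame, bpC, NULL, nTheta = 72)
  expect_true(all(is.infinite(maps0@minMap)))
  expect_true(classifyAccessible(maps0))
  expect_error(distanceMaps(matrix(0, 0, 3), frame, bpC, NULL), "empty protein")
})

test_that("classification equals the per-cell rule on constructed maps", {
  m <- new("DistanceMaps", maxMap = matrix(-Inf, 10, 72),
           minMap = matrix(Inf, 10, 72),
           thetaBreaks = seq(-pi, pi, length.out = 73))
  expect_true(classifyAccessible(m))
  m@maxMap[3, 10] <- 2.0
  m@minMap[3, 10] <- 1.5
  expect_false(classifyAccessible(m))
  m@minMap[3, 10] <- 2.5
  expect_true(classifyAccessible(m))
})

test_that("random scenes match a from-scratch double-loop oracle", {
  sc <- makeDuplexScene("ATATAGCGCATATA", seed = 0)
  site <- sceneSite(sc)
  cfg <- getFrame(sc$trajectory, 1)
  frame <- estimateSiteFrame(cfg, cbind(site@windowScaffoldIdx,
                                        site@windowStapleIdx), 6L)
  bpC <- (cfg@positions[site@windowScaffoldIdx, ] +
            cfg@positions[site@windowStapleIdx, ]) / 2
  oracleCell <- function(p, nTheta = 24) {
    rel <- p - frame@origin
    tp <- sum(rel * frame@axis)
    tAx <- as.vector(sweep(bpC, 2, frame@origin) %*% frame@axis)
    row <- which.min(abs(tp - tAx))
    theta <- atan2(sum(rel * frame@third), sum(rel * frame@ref))
    bin <- min(max(ceiling((theta + pi) / (2 * pi / nTheta)), 1), nTheta)
    c(row, bin)
  }
  set.seed(9)
  for (rep in 1:50) {
    prot <- matrix(rnorm(60, sd = 2), 20, 3)
    prot <- sweep(prot, 2, frame@origin, "+")
    env <- matrix(rnorm(60, sd = 3), 20, 3)
    env <- sweep(env, 2, frame@origin, "+")
    maps <- distanceMaps(prot, frame, bpC, env, nTheta = 24)
    ## oracle: all protein/environment pairs sharing a cell must satisfy d_p < d_e
    ok <- TRUE
    for (i in 1:20) for (j in 1:20) {
      ci <- oracleCell(prot[i, ]); cj <- oracleCell(env[j, ])
      if (all(ci == cj)) {
        dp <- sqrt(sum((prot[i, ] - bpC[ci[1], ])^2))
        de <- sqrt(sum((env[j, ] - bpC[cj[1], ])^2))
        if (dp >= de) ok <- FALSE
      }
    }
    expect_identical(classifyAccessible(maps), ok)
  }
})

test_that("an isolated duplex is fully accessible on both sides", {
  sc <- makeDuplexScene("ATATAGCGCATATA", jitter = 0.02, nFrames = 5, seed = 10)
  site <- sceneSite(sc)
  tmpl <- probeTemplate(makeProbeCloud(3, 2000, seed = 11))
  res <- siteAccessibility(sc$trajectory, site, tmpl)
  expect_equal(unname(fractions(res)), c(1, 1, 1))
  expect_identical(res@framesUsed, 5L)
  expect_identical(res@framesSkipped, 0L)
})

test_that("raft scenes reproduce their analytic block/clear labels", {
  tmpl <- probeTemplate(makeProbeCloud(3, 20000, seed = 1))
  ## permanently blocked
  scB <- makeRaftScene(nHelices = 3, gapSchedule = rep(0.5, 3), seed = 0)
  siteB <- scanRecognitionSites(scB$design, scB$topology)[[1]]
  resB <- siteAccessibility(scB$trajectory, siteB, tmpl)
  expect_equal(unname(fractions(resB)), c(0, 0, 0))
  ## permanently clear
  scC <- makeRaftScene(nHelices = 3, gapSchedule = rep(10, 3), seed = 0)
  resC <- siteAccessibility(scC$trajectory, siteB, tmpl)
  expect_equal(unname(fractions(resC)), c(1, 1, 1))
  ## alternating: exact 0.5 and per-frame booleans match the construction
  scA <- makeRaftScene(nHelices = 3, gapSchedule = rep(c(0.5, 10), 5), seed = 0)
  resA <- siteAccessibility(scA$trajectory, siteB, tmpl)
  expect_equal(unname(fractions(resA)), c(0.5, 0.5, 0.5))
  expect_identical(unname(resA@perFrame[, "scaffold"]), scA$truth$labels)
  expect_identical(unname(resA@perFrame[, "staple"]), scA$truth$labels)
})

test_that("accessibility fractions are monotone in the inter-helix gap", {
  tmpl <- probeTemplate(makeProbeCloud(3, 20000, seed = 1))
  sc <- makeRaftScene(nHelices = 3, gapSchedule = raftGapLadder(), seed = 0)
  site <- scanRecognitionSites(sc$design, sc$topology)[[1]]
  res <- siteAccessibility(sc$trajectory, site, tmpl)
  for (s in colnames(res@perFrame))
    expect_true(!is.unsorted(res@perFrame[, s]))
  expect_identical(unname(res@perFrame[, "scaffold"]), sc$truth$labels)
})

test_that("shrinking the probe radially never decreases accessibility", {
  sc <- makeRaftScene(nHelices = 3, gapSchedule = raftGapLadder(), seed = 0)
  site <- scanRecognitionSites(sc$design, sc$topology)[[1]]
  prev <- rep(-1, length(raftGapLadder()))
  for (scale in c(1, 0.5, 0.05)) {
    cloud <- makeProbeCloud(3, 5000, seed = 1)
    p <- positions(cloud)
    p[, 1:2] <- p[, 1:2] * scale     # radial shrink toward the helix axis
    cloud@positions <- p
    res <- siteAccessibility(sc$trajectory, site, probeTemplate(cloud),
                             sides = "scaffold")
    cur <- res@perFrame[, "scaffold"]
    expect_true(all(cur >= prev))
    prev <- cur
  }
  ## a point probe at the site centre is accessible in every frame
  point <- probeTemplate(makeProbeCloud(1e-9, 1, seed = 1))
  resPt <- siteAccessibility(sc$trajectory, site, point, sides = "scaffold")
  expect_true(all(resPt@perFrame[, "scaffold"] == 1))
})

test_that("r_both never exceeds either per-side fraction", {
  tmpl <- probeTemplate(makeProbeCloud(3, 5000, offset = 1, seed = 2))
  sc <- makeRaftScene(nHelices = 2, gapSchedule = seq(1.5, 4.5, length.out = 8),
                      seed = 0)
  site <- scanRecognitionSites(sc$design, sc$topology)[[1]]
  res <- siteAccessibility(sc$trajectory, site, tmpl)
  fr <- fractions(res)
  expect_lte(fr[["both"]], min(fr[["scaffold"]], fr[["staple"]]) + 1e-12)
})

test_that("local occupancy projects neighbours into the site plane", {
  sc <- makeRaftScene(nHelices = 3, gapSchedule = c(2, 4, 6), seed = 0)
  site <- scanRecognitionSites(sc$design, sc$topology)[[1]]
  n <- 14
  neighbors <- list(up = 2 * n + seq_len(2 * n), down = 4 * n + seq_len(2 * n))
  tmpl <- probeTemplate(makeProbeCloud(2, 500, seed = 3))
  occ <- localOccupancy(sc$trajectory, site, neighbors, template = tmpl)
  expect_named(occ@neighbors, c("up", "down"))
  expect_identical(dim(occ@neighbors$up), c(3L, 2L))
  ## in-plane distance of each neighbour equals its axis-to-axis distance
  D <- sc$truth$gapSchedule + 2 * 0.6
  expect_equal(unname(sqrt(rowSums(occ@neighbors$up^2))), D, tolerance = 1e-6)
  expect_equal(unname(sqrt(rowSums(occ@neighbors$down^2))), D, tolerance = 1e-6)
  ## rigid motion leaves projections unchanged
  set.seed(13)
  tr2 <- transformTrajectory(sc$trajectory, randomRotation(), c(5, 6, 7))
  occ2 <- localOccupancy(tr2, site, neighbors, template = tmpl)
  expect_equal(occ2@neighbors$up, occ@neighbors$up, tolerance = 1e-9)
  expect_true(all(c("scaffold", "staple") %in% names(occ@footprint)))
  expect_error(localOccupancy(sc$trajectory, site, list()), "empty neighbor")
})

test_that("experimental correlation matches the textbook formula", {
  th <- c(s1 = 0.2, s2 = 0.5, s3 = 0.9, s4 = 0.4)
  expect_equal(correlateWithExperiment(th, th)$correlation, 1.0)
  inv <- mean(th) - (th - mean(th))
  expect_equal(correlateWithExperiment(th, inv)$correlation, -1.0)
  set.seed(14)
  x <- runif(12); y <- runif(12)
  names(x) <- names(y) <- sprintf("s%d", 1:12)
  r <- correlateWithExperiment(x, y)$correlation
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  ## missing pairs dropped and reported; degenerate input rejected
  y2 <- y; y2[c(2, 5)] <- NA
  rr <- correlateWithExperiment(x, y2)
  expect_identical(rr$nUsed, 10L)
  expect_setequal(rr$dropped, c("s2", "s5"))
  expect_error(correlateWithExperiment(x[1:2], y[1:2]), ">= 3")
  expect_error(correlateWithExperiment(rep(0.5, 5), y[1:5]), "zero variance")
})
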