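#' @include AllClasses.R rigid.R helix.R pdb-io.R
NULL

#' Build the enzyme docking template from a crystal complex
#'
#' Collapses each crystal duplex nucleotide to one anchor, builds the
#' correspondence with the ideal helix (first chain ascending = strand 1
#' base-pair order 5' to 3'; second chain descending = strand 2), computes the
#' Kabsch transform taking the crystal anchors onto the helix anchors, and
#' applies it to the protein particles. When the duplex is longer than the
#' helix, the central helix-length stretch is used.
#'
#' @param protein protein [ParticleCloud-class] (crystal coordinates, nm).
#' @param crystalDna DNA [ParticleCloud-class] of the bound duplex.
#' @param helix an ideal [HelixModel-class] (10 bp for the standard protocol).
#' @param rmsdCeiling warn when the superposition rmsd exceeds this (nm).
#' @return A [DockingTemplate-class].
#' @export
buildDockingTemplate <- function(protein, crystalDna, helix, rmsdCeiling = 0.5) {
  res <- dnaResidueAnchors(crystalDna)
  chains <- unique(res$info$chain)
  if (length(chains) != 2)
    stop("buildDockingTemplate: crystal duplex must have exactly 2 DNA chains")
  n <- helix@nBp
  ia <- which(res$info$chain == chains[1])
  ib <- which(res$info$chain == chains[2])
  if (length(ia) < n || length(ib) < n)
    stop(sprintf("buildDockingTemplate: need >= %d bp per strand (have %d/%d)",
                 n, length(ia), length(ib)))
  ia <- ia[order(res$info$resid[ia])]
  ib <- ib[order(res$info$resid[ib], decreasing = TRUE)]  # antiparallel partner
  ## central n bp
  offA <- (length(ia) - n) %/% 2
  offB <- (length(ib) - n) %/% 2
  ia <- ia[offA + seq_len(n)]
  ib <- ib[offB + seq_len(n)]
  mobile <- res$anchors[c(ia, ib), , drop = FALSE]
  fit <- kabschSuperpose(mobile, helixAnchors(helix))
  if (fit$rmsd > rmsdCeiling)
    warning(sprintf("buildDockingTemplate: duplex superposition rmsd %.3f nm exceeds %.2f nm",
                    fit$rmsd, rmsdCeiling))
  corr <- data.frame(
    crystalChain = res$info$chain[c(ia, ib)],
    crystalResid = res$info$resid[c(ia, ib)],
    helixStrand = rep(1:2, each = n), helixBp = rep(seq_len(n), 2))
  new("DockingTemplate",
      protein = applyTransform(fit$transform, protein),
      helix = helix, correspondence = corr, rmsd = fit$rmsd,
      engagedStrand = "strand1")
}

#' Docking template from a synthetic probe cloud
#'
#' Wraps a particle cloud already expressed in the ideal-helix frame as a
#' [DockingTemplate-class] (synthetic stand-in for a crystal complex).
#'
#' @param cloud a [ParticleCloud-class] in the helix frame.
#' @param helix the [HelixModel-class] (default 10 bp).
#' @return A [DockingTemplate-class].
#' @export
probeTemplate <- function(cloud, helix = buildIdealHelix(10)) {
  n <- helix@nBp
  new("DockingTemplate", protein = cloud, helix = helix,
      correspondence = data.frame(crystalChain = NA_character_,
                                  crystalResid = NA_integer_,
                                  helixStrand = rep(1:2, each = n),
                                  helixBp = rep(seq_len(n), 2)),
      rmsd = 0, engagedStrand = "strand1")
}

#' Dock the enzyme template onto a site in one frame
#'
#' Superposes the ideal-helix anchors onto the window nucleotide positions and
#' applies the resulting transform to the template's protein particles. For
#' `side = "scaffold"` the engaged helix strand maps onto the scaffold strand;
#' for `side = "staple"` the strand-swapped correspondence (the duplex
#' pseudo-dyad flip) maps it onto the staple strand.
#'
#' @param template a [DockingTemplate-class].
#' @param config an [OxConfiguration-class].
#' @param site a [RecognitionSite-class] with a complete window.
#' @param side "scaffold" or "staple".
#' @return list with `protein` (placed [ParticleCloud-class]), `transform` and
#'   `rmsd` (nm); or `NULL` (skip signal) when a window nucleotide is unpaired.
#' @export
dockToSite <- function(template, config, site, side = c("scaffold", "staple")) {
  side <- match.arg(side)
  ws <- site@windowScaffoldIdx
  wp <- site@windowStapleIdx
  if (anyNA(ws) || anyNA(wp)) return(NULL)
  n <- template@helix@nBp
  if (length(ws) != n)
    stop(sprintf("dockToSite: window (%d bp) does not match the helix (%d bp)",
                 length(ws), n))
  targets <- if (side == "scaffold") {
    rbind(config@positions[ws, , drop = FALSE], config@positions[wp, , drop = FALSE])
  } else {
    rbind(config@positions[rev(wp), , drop = FALSE],
          config@positions[rev(ws), , drop = FALSE])
  }
  fit <- kabschSuperpose(helixAnchors(template@helix), targets)
  list(protein = applyTransform(fit$transform, template@protein),
       transform = fit$transform, rmsd = fit$rmsd)
}

#' Max/min distance maps of a docked scene
#'
#' Each particle is assigned to a cell (i, theta): i the base-pair row whose
#' centre is nearest along the site axis (particles beyond the window ends are
#' clamped to the end rows) and theta its azimuth about the axis in the local
#' frame, binned over (-pi, pi]. The cell distance is the Euclidean distance
#' from the assigned base-pair centre. The max map takes the farthest protein
#' particle per cell (-Inf where empty); the min map the nearest environment
#' particle (+Inf where empty).
#'
#' @param protein placed protein particles (matrix or [ParticleCloud-class]).
#' @param siteFrame the site [LocalFrame-class].
#' @param bpCenters nBp x 3 matrix of window base-pair centres (nm).
#' @param environment adjacent-DNA particles (matrix, [ParticleCloud-class], or
#'   `NULL`/zero rows for none).
#' @param nTheta number of azimuth bins (default 72, i.e. 5 degrees).
#' @return A [DistanceMaps-class].
#' @export
distanceMaps <- function(protein, siteFrame, bpCenters, environment = NULL,
                         nTheta = 72) {
  if (is(protein, "ParticleCloud")) protein <- protein@positions
  if (is(environment, "ParticleCloud")) environment <- environment@positions
  if (is.null(protein) || nrow(protein) == 0)
    stop("distanceMaps: empty protein cloud")
  nBp <- nrow(bpCenters)
  thetaBreaks <- seq(-pi, pi, length.out = nTheta + 1)
  tAxis <- as.vector(sweep(bpCenters, 2, siteFrame@origin) %*% siteFrame@axis)

  assign <- function(pts) {
    rel <- sweep(pts, 2, siteFrame@origin)
    tp <- as.vector(rel %*% siteFrame@axis)
    row <- apply(abs(outer(tp, tAxis, "-")), 1, which.min)
    y <- as.vector(rel %*% siteFrame@ref)
    z <- as.vector(rel %*% siteFrame@third)
    theta <- atan2(z, y)
    bin <- pmin(pmax(findInterval(theta, thetaBreaks, rightmost.closed = TRUE), 1L),
                nTheta)
    d <- sqrt(rowSums((pts - bpCenters[row, , drop = FALSE])^2))
    list(cell = (bin - 1L) * nBp + row, d = d)
  }

  maxMap <- matrix(-Inf, nBp, nTheta)
  pa <- assign(protein)
  mx <- tapply(pa$d, pa$cell, max)
  maxMap[as.integer(names(mx))] <- mx
  minMap <- matrix(Inf, nBp, nTheta)
  if (!is.null(environment) && nrow(environment) > 0) {
    ea <- assign(environment)
    mn <- tapply(ea$d, ea$cell, min)
    minMap[as.integer(names(mn))] <- mn
  }
  new("DistanceMaps", maxMap = maxMap, minMap = minMap, thetaBreaks = thetaBreaks)
}

#' Accessibility criterion on a pair of distance maps
#'
#' `TRUE` iff max < min in every cell. Cells with no protein particle
#' (max = -Inf) never block; cells with no environment particle (min = +Inf)
#' never block.
#'
#' @param maps a [DistanceMaps-class].
#' @return logical(1).
#' @export
classifyAccessible <- function(maps) {
  all(maps@maxMap < maps@minMap)
}

## nucleotide indices excluded from the environment: the window plus marginBp
## base pairs along the same duplex on each side (both strands)
.siteExclusion <- function(topology, site, marginBp = 2) {
  ws <- site@windowScaffoldIdx
  wp <- site@windowStapleIdx
  excl <- c(ws, wp)
  walk <- function(start, slotName) {
    out <- integer(0)
    cur <- start
    for (k in seq_len(marginBp)) {
      cur <- slot(topology, slotName)[cur]
      if (is.na(cur)) break
      out <- c(out, cur)
    }
    out
  }
  ext <- c(walk(ws[1], "neighbor5"), walk(ws[length(ws)], "neighbor3"))
  if (length(topology@pairing))
    ext <- c(ext, topology@pairing[ext])
  sort(unique(c(excl, ext[!is.na(ext)])))
}

#' Steric accessibility of one site over a trajectory
#'
#' For every frame and requested strand side, docks the enzyme template onto
#' the site, builds the max/min distance maps against all adjacent DNA
#' interaction centres (every nucleotide outside the window plus a `marginBp`
#' exclusion margin along the same duplex) and classifies the frame
#' accessible/inaccessible. Fractions are computed over frames where docking
#' succeeded; skipped frames are counted separately.
#'
#' @param traj an [OxTrajectory-class].
#' @param site a [RecognitionSite-class].
#' @param template a [DockingTemplate-class].
#' @param sides character subset of c("scaffold", "staple").
#' @param nTheta azimuth bins for the maps (default 72).
#' @param marginBp same-duplex exclusion margin in bp (default 2).
#' @param referenceNucleotide nucleotide whose versor fixes the local frame's
#'   reference direction (default: first motif nucleotide).
#' @return An [AccessibilityResult-class]; fractions named by side plus
#'   `"both"` (both sides accessible in the same frame) when both sides run.
#' @export
siteAccessibility <- function(traj, site, template,
                              sides = c("scaffold", "staple"),
                              nTheta = 72, marginBp = 2,
                              referenceNucleotide = site@scaffoldIdx[1]) {
  sides <- match.arg(sides, c("scaffold", "staple"), several.ok = TRUE)
  tt <- nFrames(traj)
  if (tt < 1) stop("siteAccessibility: empty trajectory")
  top <- traj@topology
  ws <- site@windowScaffoldIdx
  wp <- site@windowStapleIdx
  perFrame <- matrix(NA, tt, length(sides), dimnames = list(NULL, sides))
  if (!anyNA(ws) && !anyNA(wp)) {
    envIdx <- setdiff(seq_len(top@nNucleotides), .siteExclusion(top, site, marginBp))
    for (t in seq_len(tt)) {
      cfg <- getFrame(traj, t)
      frame <- estimateSiteFrame(cfg, cbind(ws, wp), referenceNucleotide)
      bpC <- (cfg@positions[ws, , drop = FALSE] + cfg@positions[wp, , drop = FALSE]) / 2
      env <- if (length(envIdx)) {
        interactionCenters(cfg@positions[envIdx, , drop = FALSE],
                           cfg@bbVersor[envIdx, , drop = FALSE])
      } else NULL
      for (s in sides) {
        placed <- dockToSite(template, cfg, site, s)
        if (is.null(placed)) next
        maps <- distanceMaps(placed$protein, frame, bpC, env, nTheta = nTheta)
        perFrame[t, s] <- classifyAccessible(maps)
      }
    }
  }
  used <- sum(stats::complete.cases(perFrame))
  if (used == 0)
    stop("siteAccessibility: all frames skipped (unpaired or truncated window)")
  fr <- colMeans(perFrame, na.rm = TRUE)
  if (length(sides) > 1) {
    ok <- stats::complete.cases(perFrame)
    fr <- c(fr, both = mean(apply(perFrame[ok, , drop = FALSE], 1, all)))
  }
  new("AccessibilityResult", siteId = site@id, perFrame = perFrame,
      fractions = fr, framesUsed = as.integer(used),
      framesSkipped = as.integer(tt - used))
}

#' Neighbourhood occupancy in the site plane
#'
#' Projects, per frame, the centre of mass of each neighbouring helix onto the
#' plane perpendicular to the site axis, expressed in the site's local frame;
#' the enzyme footprint is the convex hull of the placed protein projected in
#' the first frame, per side.
#'
#' @param traj an [OxTrajectory-class].
#' @param site a [RecognitionSite-class].
#' @param neighbors named list of nucleotide index vectors, one per adjacent
#'   helix (nonempty).
#' @param template optional [DockingTemplate-class] for the footprint.
#' @param sides sides for the footprint.
#' @param referenceNucleotide see [siteAccessibility()].
#' @return A [LocalOccupancy-class].
#' @export
localOccupancy <- function(traj, site, neighbors, template = NULL,
                           sides = c("scaffold", "staple"),
                           referenceNucleotide = site@scaffoldIdx[1]) {
  if (!length(neighbors) || any(!lengths(neighbors)))
    stop("localOccupancy: empty neighbor set")
  if (is.null(names(neighbors)))
    names(neighbors) <- sprintf("neighbor%d", seq_along(neighbors))
  ws <- site@windowScaffoldIdx
  wp <- site@windowStapleIdx
  if (anyNA(ws) || anyNA(wp)) stop("localOccupancy: incomplete site window")
  tt <- nFrames(traj)
  proj <- lapply(neighbors, function(x) matrix(0, tt, 2,
                                               dimnames = list(NULL, c("y", "z"))))
  for (t in seq_len(tt)) {
    cfg <- getFrame(traj, t)
    frame <- estimateSiteFrame(cfg, cbind(ws, wp), referenceNucleotide)
    for (nb in names(neighbors)) {
      com <- colMeans(cfg@positions[neighbors[[nb]], , drop = FALSE])
      loc <- toLocalFrame(frame, matrix(com, 1, 3))
      proj[[nb]][t, ] <- loc[1, 2:3]
    }
  }
  footprint <- list()
  if (!is.null(template)) {
    cfg <- getFrame(traj, 1)
    frame <- estimateSiteFrame(cfg, cbind(ws, wp), referenceNucleotide)
    for (s in sides) {
      placed <- dockToSite(template, cfg, site, s)
      if (is.null(placed)) next
      pts <- toLocalFrame(frame, placed$protein@positions)[, 2:3, drop = FALSE]
      footprint[[s]] <- pts[grDevices::chull(pts), , drop = FALSE]
    }
  }
  new("LocalOccupancy", siteId = site@id, neighbors = proj, footprint = footprint)
}

#' Correlate theoretical accessibility with experimental cleavage
#'
#' Pearson correlation of paired per-site vectors; sites flagged as crossover
#' overlaps must be excluded by the caller before pairing. Pairs with missing
#' experimental values are dropped and reported.
#'
#' @param theory named numeric vector of theoretical fractions.
#' @param experiment named numeric vector of experimental cleaved fractions.
#' @return list with `correlation`, `nUsed` and `dropped` (site names).
#' @export
correlateWithExperiment <- function(theory, experiment) {
  if (!is.null(names(theory)) && !is.null(names(experiment))) {
    common <- intersect(names(theory), names(experiment))
    theory <- theory[common]; experiment <- experiment[common]
  }
  if (length(theory) != length(experiment))
    stop("correlateWithExperiment: unpaired vectors")
  keep <- !is.na(theory) & !is.na(experiment)
  dropped <- names(theory)[!keep]
  x <- theory[keep]; y <- experiment[keep]
  if (length(x) < 3) stop("correlateWithExperiment: need >= 3 paired sites")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlateWithExperiment: undefined correlation (zero variance)")
  list(correlation = stats::cor(x, y), nUsed = length(x), dropped = dropped)
}
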