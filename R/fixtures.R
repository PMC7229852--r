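#' @include AllClasses.R helix.R oxdna-io.R
NULL

## All generators are deterministic given (parameters, seed): they set the RNG
## locally and restore the caller's state on exit.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

## duplex topology for one or more helices: strands come in (scaffold, staple)
## pairs per helix; staple nucleotides are stored in their own 5'->3' order
.duplexTopology <- function(sequences) {
  strand <- integer(0); base <- character(0)
  n3 <- integer(0); n5 <- integer(0); pairing <- integer(0)
  off <- 0L; sid <- 0L
  for (seqs in sequences) {
    n <- nchar(seqs)
    b1 <- strsplit(seqs, "")[[1]]
    b2 <- rev(unname(.complement[b1]))          # staple 5'->3'
    sid <- sid + 1L
    strand <- c(strand, rep(sid, n), rep(sid + 1L, n))
    sid <- sid + 1L
    base <- c(base, b1, b2)
    idx1 <- off + seq_len(n)
    idx2 <- off + n + seq_len(n)
    n3 <- c(n3, c(idx1[-1], NA), c(idx2[-1], NA))
    n5 <- c(n5, c(NA, idx1[-n]), c(NA, idx2[-n]))
    pairing <- c(pairing, rev(idx2), rev(idx1))  # bp i <-> staple slot n+1-i
    off <- off + 2L * n
  }
  new("OxTopology", nNucleotides = length(base), nStrands = sid,
      strandId = strand, base = base, neighbor3 = as.integer(n3),
      neighbor5 = as.integer(n5), pairing = as.integer(pairing),
      circular = rep(FALSE, sid))
}

## static coordinates of one duplex from a helix model, in topology order
.duplexCoords <- function(helix) {
  n <- helix@nBp
  list(positions = rbind(helix@strand1, helix@strand2[n:1, , drop = FALSE]),
       bb = rbind(helix@bbVersor1, helix@bbVersor2[n:1, , drop = FALSE]),
       norm = rbind(helix@normVersor1, helix@normVersor2[n:1, , drop = FALSE]))
}

#' Isolated-duplex scene with Gaussian jitter
#'
#' An ideal duplex repeated over `nFrames` frames with isotropic Gaussian
#' jitter of standard deviation `jitter` per coordinate. Emulates an isolated,
#' fully accessible recognition site.
#'
#' @param sequence scaffold-strand sequence (>= 10 nt).
#' @param rise,twist helix parameters (see [buildIdealHelix()]).
#' @param jitter per-coordinate noise sd, nm (>= 0).
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @return list with `topology`, `trajectory` and `truth` (helix model, jitter).
#' @export
makeDuplexScene <- function(sequence, rise = 0.34, twist = 360 / 10.5,
                            jitter = 0, nFrames = 1, seed = 0) {
  if (nchar(sequence) < 10) stop("makeDuplexScene: sequence must be >= 10 nt")
  if (jitter < 0) stop("makeDuplexScene: jitter must be >= 0")
  helix <- buildIdealHelix(nchar(sequence), sequence, rise, twist)
  top <- .duplexTopology(list(sequence))
  crd <- .duplexCoords(helix)
  n <- top@nNucleotides
  traj <- .withSeed(seed, {
    pos <- array(0, c(n, 3, nFrames))
    bb <- array(rep(crd$bb, nFrames), c(n, 3, nFrames))
    nv <- array(rep(crd$norm, nFrames), c(n, 3, nFrames))
    for (t in seq_len(nFrames))
      pos[, , t] <- crd$positions + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
    new("OxTrajectory", topology = top, positions = pos, bbVersors = bb,
        normVersors = nv, times = (seq_len(nFrames) - 1) * 7,
        boxes = matrix(100, 3, nFrames), lengthUnit = OXDNA_LENGTH_UNIT)
  })
  list(topology = top, trajectory = traj,
       truth = list(helix = helix, jitter = jitter, pairing = top@pairing))
}

#' Multi-helix raft scene with a scheduled inter-helix gap
#'
#' Parallel duplexes in a plane: the central helix carries one recognition
#' motif; the neighbours rigidly follow a per-frame surface-to-surface gap
#' schedule (gap = axis distance minus one helix diameter). The ground truth
#' labels each frame clear/blocked for a probe of radial extent `probeExtent`
#' docked on the motif: the nearest environment interaction centre approaches
#' the site axis to `gap + radius - backboneOffset`, so the analytic threshold
#' is `gap > probeExtent - (radius - backboneOffset)`. Schedule values within
#' about 0.3 nm of the threshold are ambiguous at finite probe sampling and
#' should be avoided.
#'
#' @param nHelices number of helices (>= 2; the motif helix plus neighbours).
#' @param helixLengthBp helix length (default 14 = 10 bp window + 2 bp margins).
#' @param gapSchedule numeric vector of per-frame gaps (nm, >= 0); its length
#'   sets the frame count.
#' @param probeExtent radial extent (nm) assumed for the ground-truth labels.
#' @param motif recognition motif placed centrally on the middle helix.
#' @param seed RNG seed (neighbour sequences).
#' @return list with `topology`, `trajectory`, `design`, `siteWindow` (bp pair
#'   matrix), and `truth` (`labels`, `threshold`, `gapSchedule`).
#' @export
makeRaftScene <- function(nHelices = 3, helixLengthBp = 14, gapSchedule,
                          probeExtent = 3, motif = "GCGC", seed = 0) {
  if (nHelices < 2) stop("makeRaftScene: need at least 2 helices")
  if (any(gapSchedule < 0)) stop("makeRaftScene: gaps must be >= 0")
  nFrames <- length(gapSchedule)
  if (!nFrames) stop("makeRaftScene: empty gap schedule")
  n <- helixLengthBp
  mlen <- nchar(motif)
  if (n < mlen + 6) stop("makeRaftScene: helix too short for the motif window")
  ## motif centred: flankLeft 3 within the 10-bp window centred on the helix
  wStart <- (n - 10L) %/% 2L + 1L
  mStart <- wStart + 3L
  flank1 <- strrep("AT", 20)
  centralSeq <- paste0(substr(flank1, 1, mStart - 1), motif,
                       substr(flank1, 1, n - mStart - mlen + 1))
  centralSeq <- substr(centralSeq, 1, n)

  seqs <- .withSeed(seed, {
    c(list(centralSeq),
      replicate(nHelices - 1,
                paste(sample(c("A", "T"), n, replace = TRUE), collapse = ""),
                simplify = FALSE))
  })
  top <- .duplexTopology(seqs)
  helices <- lapply(seqs, function(s) buildIdealHelix(n, s))
  coords <- lapply(helices, .duplexCoords)

  ## neighbour offsets: alternate sides of the central helix
  sideOf <- function(k) (-1)^k * ceiling(k / 2)   # 1,-1,2,-2,... -> +1,-1,...
  r <- .cg$radius
  nn <- top@nNucleotides
  pos <- array(0, c(nn, 3, nFrames))
  bb <- array(0, c(nn, 3, nFrames))
  nv <- array(0, c(nn, 3, nFrames))
  per <- 2L * n
  for (t in seq_len(nFrames)) {
    D <- gapSchedule[t] + 2 * r
    for (h in seq_len(nHelices)) {
      rows <- (h - 1L) * per + seq_len(per)
      shift <- if (h == 1) 0 else sideOf(h - 1) * D
      p <- coords[[h]]$positions
      p[, 2] <- p[, 2] + shift
      pos[rows, , t] <- p
      bb[rows, , t] <- coords[[h]]$bb
      nv[rows, , t] <- coords[[h]]$norm
    }
  }
  traj <- new("OxTrajectory", topology = top, positions = pos, bbVersors = bb,
              normVersors = nv, times = (seq_len(nFrames) - 1) * 7,
              boxes = matrix(200, 3, nFrames), lengthUnit = OXDNA_LENGTH_UNIT)

  design <- .raftDesign(centralSeq)
  threshold <- probeExtent - (.cg$radius - .cg$backboneOffset)
  window <- cbind(scaffold = wStart:(wStart + 9L),
                  staple = top@pairing[wStart:(wStart + 9L)])
  list(topology = top, trajectory = traj, design = design,
       siteWindow = window,
       truth = list(labels = gapSchedule > threshold, threshold = threshold,
                    gapSchedule = gapSchedule, probeExtent = probeExtent,
                    motifStart = mStart))
}

## minimal one-helix design map for the raft's central duplex
.raftDesign <- function(sequence) {
  n <- nchar(sequence)
  new("DesignMap",
      scaffoldPath = data.frame(helix = 0L, pos = seq_len(n) - 1L),
      staples = list(data.frame(helix = 0L, pos = rev(seq_len(n) - 1L))),
      crossovers = data.frame(helix = integer(0), pos = integer(0),
                              partnerHelix = integer(0), kind = character(0)),
      scaffoldSeq = sequence, pairedMask = rep(TRUE, n),
      omittedStaples = integer(0))
}

#' Trajectory with a planted double-well collective coordinate
#'
#' Samples a collective coordinate by overdamped Euler-Maruyama dynamics in
#' the quartic double well U(s) = barrier * ((s - c)^2 - m^2)^2 / m^4 (+ an
#' optional linear tilt), with kBT = 1, and emits frames
#' `base + a_t * mode + noise`. The planted mode is orthogonalized against the
#' six rigid-body motions of the base structure so alignment cannot remove it.
#'
#' @param base N x 3 base structure (nm).
#' @param mode unit 3N vector, or `NULL` to draw one at random.
#' @param barrier well-to-barrier height (kBT, > 0).
#' @param minima numeric(2), well positions (nm).
#' @param tilt energy offset added linearly from the first to the second
#'   minimum (kBT; 0 = symmetric wells).
#' @param noise isotropic per-coordinate noise sd orthogonal to the mode (nm).
#' @param nFrames frames to record.
#' @param seed RNG seed.
#' @param dt integration step; `stride` steps are taken per recorded frame.
#' @param stride steps between recorded frames.
#' @return list with `trajectory`, `topology` and `truth` (`a` per frame,
#'   `labels`, `mode`, potential parameters, `potential(s)` function).
#' @export
makeTwoStateTrajectory <- function(base, mode = NULL, barrier = 3,
                                   minima = c(-2, 2), tilt = 0, noise = 0,
                                   nFrames = 1000, seed = 0,
                                   dt = 0.01, stride = 10) {
  if (barrier <= 0) stop("makeTwoStateTrajectory: barrier must be > 0")
  base <- as.matrix(base)
  N <- nrow(base)
  c0 <- mean(minima)
  m <- abs(diff(minima)) / 2
  U <- function(s) barrier * ((s - c0)^2 - m^2)^2 / m^4 + tilt * (s - c0) / (2 * m)
  dU <- function(s) 4 * barrier * (s - c0) * ((s - c0)^2 - m^2) / m^4 + tilt / (2 * m)

  out <- .withSeed(seed, {
    if (is.null(mode)) mode <- stats::rnorm(3 * N)
    else if (abs(sqrt(sum(mode^2)) - 1) > 1e-6)
      stop("makeTwoStateTrajectory: mode must be unit norm")
    mode <- .removeRigidComponents(mode, base)

    s <- minima[1]
    a <- numeric(nFrames)
    sq <- sqrt(2 * dt)
    for (f in seq_len(nFrames)) {
      eta <- stats::rnorm(stride)
      for (k in seq_len(stride)) s <- s - dU(s) * dt + sq * eta[k]
      a[f] <- s
    }
    modeMat <- .unflatten(mode)
    pos <- array(0, c(N, 3, nFrames))
    for (f in seq_len(nFrames)) {
      fr <- base + a[f] * modeMat
      if (noise > 0) fr <- fr + matrix(stats::rnorm(3 * N, sd = noise), N, 3)
      pos[, , f] <- fr
    }
    list(a = a, mode = mode, pos = pos)
  })

  top <- new("OxTopology", nNucleotides = N, nStrands = 1L,
             strandId = rep(1L, N), base = rep("A", N),
             neighbor3 = c(2:N, NA), neighbor5 = c(NA, 1:(N - 1)),
             pairing = integer(0), circular = FALSE)
  bb <- array(rep(c(1, 0, 0), each = N), c(N, 3, nFrames))
  nv <- array(rep(c(0, 0, 1), each = N), c(N, 3, nFrames))
  traj <- new("OxTrajectory", topology = top, positions = out$pos,
              bbVersors = bb, normVersors = nv,
              times = (seq_len(nFrames) - 1) * 7,
              boxes = matrix(1000, 3, nFrames), lengthUnit = OXDNA_LENGTH_UNIT)
  list(trajectory = traj, topology = top,
       truth = list(a = out$a, labels = out$a > c0, mode = out$mode,
                    barrier = barrier, minima = minima, tilt = tilt,
                    noise = noise, potential = U))
}

## project a 3N vector out of the span of the 6 rigid-body motions of `base`
## and renormalize
.removeRigidComponents <- function(mode, base) {
  N <- nrow(base)
  ctr <- sweep(base, 2, colMeans(base))
  basis <- matrix(0, 3 * N, 6)
  for (k in 1:3) basis[seq(k, 3 * N, by = 3), k] <- 1            # translations
  ex <- diag(3)
  for (k in 1:3) {                                               # rotations
    rot <- t(apply(ctr, 1, function(r) c(ex[k, 2] * r[3] - ex[k, 3] * r[2],
                                         ex[k, 3] * r[1] - ex[k, 1] * r[3],
                                         ex[k, 1] * r[2] - ex[k, 2] * r[1])))
    basis[, 3 + k] <- .flatten(rot)
  }
  q <- qr.Q(qr(basis))
  mode <- mode - q %*% crossprod(q, mode)
  n <- sqrt(sum(mode^2))
  if (n < 1e-8) stop("planted mode lies in the rigid-body span")
  as.vector(mode / n)
}

#' Uniform probe particle cloud
#'
#' Particles filling a ball of radius `extent`, centred `offset` nm from the
#' helix axis at the axial midpoint of a 10-bp window. Stands in for an enzyme
#' when no crystal structure is supplied (synthetic probe).
#'
#' @param extent ball radius, nm (> 0).
#' @param nParticles number of particles (> 0).
#' @param offset radial offset of the ball centre from the helix axis (nm).
#' @param seed RNG seed.
#' @param axialCenter axial position of the centre (default: midpoint of a
#'   10-bp window at 0.34 nm rise).
#' @return A protein [ParticleCloud-class] in the ideal-helix frame.
#' @export
makeProbeCloud <- function(extent, nParticles, offset = 0, seed = 0,
                           axialCenter = 4.5 * 0.34) {
  if (extent <= 0) stop("makeProbeCloud: extent must be > 0")
  if (nParticles < 1) stop("makeProbeCloud: need at least 1 particle")
  pts <- .withSeed(seed, {
    u <- matrix(stats::rnorm(3 * nParticles), nParticles, 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- extent * stats::runif(nParticles)^(1 / 3)
    u * rad
  })
  pts <- sweep(pts, 2, c(offset, 0, axialCenter), "+")
  new("ParticleCloud", positions = pts,
      labels = data.frame(chain = "P", resid = seq_len(nParticles), atom = "C",
                          stringsAsFactors = FALSE),
      role = "protein")
}

#' Write a toy two-helix cadnano design
#'
#' A square-lattice design with a U-shaped scaffold (helix 0 forward, one
#' scaffold crossover at the far end, helix 1 back) and staples crossing
#' between the helices at the given positions. Used for format tests and
#' synthetic worked examples.
#'
#' @param path output JSON path.
#' @param cells positions per helix (multiple of 32 for square lattice).
#' @param stapleCross 0-based positions of single staple crossovers.
#' @return `path`, invisibly; the routed scaffold length is `2 * cells`.
#' @export
writeToyCadnano <- function(path, cells = 64, stapleCross = c(16)) {
  if (cells %% 32 != 0) stop("writeToyCadnano: cells must be a multiple of 32")
  stapleCross <- sort(as.integer(stapleCross))
  if (any(stapleCross < 1 | stapleCross > cells - 2))
    stop("writeToyCadnano: crossover positions out of range")
  none <- c(-1L, -1L, -1L, -1L)
  scaf0 <- scaf1 <- stap0 <- stap1 <- rep(list(none), cells)
  for (p in 0:(cells - 1)) {
    scaf0[[p + 1]] <- c(if (p == 0) c(-1L, -1L) else c(0L, p - 1L),
                        if (p == cells - 1) c(1L, p) else c(0L, p + 1L))
    scaf1[[p + 1]] <- c(if (p == cells - 1) c(0L, p) else c(1L, p + 1L),
                        if (p == 0) c(-1L, -1L) else c(1L, p - 1L))
  }
  ## staples: one per inter-crossover segment; helix1 runs 5'->3' increasing,
  ## helix0 decreasing; each listed position x hosts the (1,x) -> (0,x) pass
  bounds <- c(-1L, stapleCross, cells - 1L)
  for (i in seq_along(stapleCross)) {
    lo <- bounds[i] + 1L; x <- stapleCross[i]
    for (p in lo:x)
      stap1[[p + 1]] <- c(if (p == lo) c(-1L, -1L) else c(1L, p - 1L),
                          if (p == x) c(0L, p) else c(1L, p + 1L))
    for (p in lo:x)
      stap0[[p + 1]] <- c(if (p == x) c(1L, p) else c(0L, p + 1L),
                          if (p == lo) c(-1L, -1L) else c(0L, p - 1L))
  }
  lo <- stapleCross[length(stapleCross)] + 1L; hi <- cells - 1L
  for (p in lo:hi) {   # tail segments, no crossover
    stap0[[p + 1]] <- c(if (p == hi) c(-1L, -1L) else c(0L, p + 1L),
                        if (p == lo) c(-1L, -1L) else c(0L, p - 1L))
    stap1[[p + 1]] <- c(if (p == lo) c(-1L, -1L) else c(1L, p - 1L),
                        if (p == hi) c(-1L, -1L) else c(1L, p + 1L))
  }
  vs <- lapply(0:1, function(h) list(
    num = h, row = 0L, col = h,
    scaf = if (h == 0) scaf0 else scaf1,
    stap = if (h == 0) stap0 else stap1,
    loop = rep(0L, cells), skip = rep(0L, cells),
    stap_colors = list(), scafLoop = list(), stapLoop = list()))
  jsonlite::write_json(list(name = "toy", vstrands = vs), path,
                       auto_unbox = TRUE)
  invisible(path)
}
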