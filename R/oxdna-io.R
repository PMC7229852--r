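#' @include AllClasses.R
NULL

## Default oxDNA length unit in nm, applied once at the file boundary so that
## every in-memory coordinate is in nm.
OXDNA_LENGTH_UNIT <- 0.8518
## Intrinsic time unit (ns); stored as metadata only, no analysis depends on it.
OXDNA_TAU_NS <- 0.7

#' Read an oxDNA topology file
#'
#' Classic oxDNA topology dialect: a header line with nucleotide and strand
#' counts, then one line per nucleotide with `strand base neighbor3 neighbor5`
#' (0-based, -1 for none). Indices are converted to 1-based.
#'
#' @param path file path.
#' @return An [OxTopology-class] (no pairing table; oxDNA topologies carry
#'   none — see [inferPairing()]).
#' @export
readOxTopology <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("readOxTopology: empty file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("readOxTopology: malformed header (line 1)")
  n <- as.integer(hdr[1]); ns <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) != n)
    stop(sprintf("readOxTopology: header declares %d nucleotides but file has %d records",
                 n, length(body)))
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) < 4)
  if (length(bad))
    stop(sprintf("readOxTopology: malformed line %d", bad[1] + 1L))
  strand <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1)))
  base <- toupper(vapply(fields, `[`, "", 2))
  n3 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  n5 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
  bad <- which(is.na(strand) | is.na(n3) | is.na(n5) | !base %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("readOxTopology: malformed line %d", bad[1] + 1L))
  if (any(n3 >= n) || any(n5 >= n) || any(n3 < -1) || any(n5 < -1))
    stop("readOxTopology: neighbor index out of range (dangling link)")
  n3 <- ifelse(n3 < 0, NA_integer_, n3 + 1L)
  n5 <- ifelse(n5 < 0, NA_integer_, n5 + 1L)
  circular <- vapply(seq_len(ns), function(s) {
    idx <- which(strand == s)
    length(idx) > 0 && !anyNA(n3[idx]) && !anyNA(n5[idx])
  }, logical(1))
  new("OxTopology", nNucleotides = n, nStrands = ns, strandId = strand,
      base = base, neighbor3 = as.integer(n3), neighbor5 = as.integer(n5),
      pairing = integer(0), circular = circular)
}

#' Write an oxDNA topology file
#'
#' @param topology an [OxTopology-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOxTopology <- function(topology, path) {
  n3 <- ifelse(is.na(topology@neighbor3), -1L, topology@neighbor3 - 1L)
  n5 <- ifelse(is.na(topology@neighbor5), -1L, topology@neighbor5 - 1L)
  lines <- c(sprintf("%d %d", topology@nNucleotides, topology@nStrands),
             sprintf("%d %s %d %d", topology@strandId, topology@base, n3, n5))
  writeLines(lines, path)
  invisible(path)
}

#' Read an oxDNA configuration/trajectory file
#'
#' Parses concatenated configuration blocks (`t = ...`, `b = ...`, `E = ...`
#' headers followed by one line per nucleotide: position, backbone-base versor,
#' base-normal versor and optional velocities). Frames are read sequentially
#' from the connection, one block at a time; positions and box lengths are
#' multiplied by `lengthUnit` (nm per oxDNA unit), versors are left unscaled.
#'
#' @param path file path.
#' @param topology the matching [OxTopology-class].
#' @param lengthUnit nm per oxDNA length unit (default `r OXDNA_LENGTH_UNIT`).
#' @param callback optional `function(config, ordinal)` invoked per frame; when
#'   given, frames are not accumulated and `NULL` is returned.
#' @return An [OxTrajectory-class] (or `NULL` when `callback` is used).
#' @export
readOxTrajectory <- function(path, topology, lengthUnit = OXDNA_LENGTH_UNIT,
                             callback = NULL) {
  n <- topology@nNucleotides
  con <- file(path, open = "r")
  on.exit(close(con))
  frames <- list()
  ord <- 0L
  repeat {
    hdr <- readLines(con, n = 3)
    if (length(hdr) == 0) break
    ord <- ord + 1L
    if (length(hdr) < 3 || !grepl("^\\s*t\\s*=", hdr[1]) ||
        !grepl("^\\s*b\\s*=", hdr[2]))
      stop(sprintf("readOxTrajectory: malformed header of frame %d", ord))
    tval <- as.numeric(sub("^\\s*t\\s*=\\s*", "", hdr[1]))
    box <- as.numeric(strsplit(trimws(sub("^\\s*b\\s*=\\s*", "", hdr[2])), "\\s+")[[1]])
    body <- readLines(con, n = n)
    if (length(body) < n)
      stop(sprintf("readOxTrajectory: truncated frame %d (%d of %d records)",
                   ord, length(body), n))
    vals <- strsplit(trimws(body), "\\s+")
    ncol <- lengths(vals)
    if (any(ncol < 9))
      stop(sprintf("readOxTrajectory: frame %d has records with fewer than 9 fields", ord))
    m <- matrix(as.numeric(unlist(lapply(vals, `[`, 1:9))), nrow = n, byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("readOxTrajectory: non-numeric record in frame %d", ord))
    cfg <- new("OxConfiguration",
               time = tval, box = box[1:3] * lengthUnit,
               positions = m[, 1:3, drop = FALSE] * lengthUnit,
               bbVersor = m[, 4:6, drop = FALSE],
               normVersor = m[, 7:9, drop = FALSE])
    if (!is.null(callback)) callback(cfg, ord) else frames[[ord]] <- cfg
  }
  if (ord == 0) stop("readOxTrajectory: no frames found")
  if (!is.null(callback)) return(invisible(NULL))
  framesToTrajectory(topology, frames, lengthUnit = lengthUnit)
}

#' Assemble an [OxTrajectory-class] from configurations
#'
#' @param topology an [OxTopology-class].
#' @param frames list of [OxConfiguration-class], timestamps strictly increasing.
#' @param lengthUnit nm per oxDNA unit recorded as metadata.
#' @return An [OxTrajectory-class].
#' @export
framesToTrajectory <- function(topology, frames, lengthUnit = OXDNA_LENGTH_UNIT) {
  n <- topology@nNucleotides
  tt <- length(frames)
  pos <- array(0, c(n, 3, tt))
  bb <- array(0, c(n, 3, tt))
  nv <- array(0, c(n, 3, tt))
  boxes <- matrix(0, 3, tt)
  times <- numeric(tt)
  for (k in seq_len(tt)) {
    f <- frames[[k]]
    pos[, , k] <- f@positions
    bb[, , k] <- f@bbVersor
    nv[, , k] <- f@normVersor
    boxes[, k] <- f@box
    times[k] <- f@time
  }
  new("OxTrajectory", topology = topology, positions = pos, bbVersors = bb,
      normVersors = nv, times = times, boxes = boxes, lengthUnit = lengthUnit)
}

#' Write an oxDNA configuration/trajectory file
#'
#' Inverse of [readOxTrajectory()]: positions and box lengths are divided by
#' the trajectory's `lengthUnit`; velocity columns are written as zeros.
#'
#' @param traj an [OxTrajectory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOxTrajectory <- function(traj, path) {
  u <- traj@lengthUnit
  con <- file(path, open = "w")
  on.exit(close(con))
  for (k in seq_len(nFrames(traj))) {
    writeLines(c(sprintf("t = %.10g", traj@times[k]),
                 paste("b =", paste(sprintf("%.10g", traj@boxes[, k] / u), collapse = " ")),
                 "E = 0 0 0"), con)
    m <- cbind(traj@positions[, , k] / u, traj@bbVersors[, , k],
               traj@normVersors[, , k], matrix(0, nNucleotides(traj), 6))
    writeLines(apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Geometric base-pairing fallback
#'
#' oxDNA topology files carry no pairing table. When no design map is
#' available, pair nucleotides whose hydrogen-bonding sites (see
#' [interactionCenters()]) are mutually nearest and closer than `threshold`,
#' with antiparallel base normals and complementary bases.
#'
#' @param topology an [OxTopology-class].
#' @param config an [OxConfiguration-class] used for the geometry.
#' @param threshold nm (default 0.15).
#' @return The topology with its `pairing` slot filled.
#' @export
inferPairing <- function(topology, config, threshold = 0.15) {
  n <- topology@nNucleotides
  bs <- config@positions + .cg$baseOffset * config@bbVersor
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  d2 <- as.matrix(stats::dist(bs))^2
  diag(d2) <- Inf
  antipar <- tcrossprod(config@normVersor) < 0
  okbase <- outer(comp[topology@base], topology@base, "==")
  d2[!(antipar & okbase)] <- Inf
  nearest <- apply(d2, 1, which.min)
  dmin <- d2[cbind(seq_len(n), nearest)]
  pairing <- rep(NA_integer_, n)
  ok <- which(dmin < threshold^2 & nearest[nearest] == seq_len(n))
  pairing[ok] <- as.integer(nearest[ok])
  topology@pairing <- pairing
  validObject(topology)
  topology
}

#' Scaffold nucleotide order
#'
#' Nucleotide indices of one strand ordered 5' to 3' by following the
#' neighbour links. For a circular strand the walk starts at the
#' lowest-numbered nucleotide.
#'
#' @param topology an [OxTopology-class].
#' @param strand strand id; default the longest strand (the scaffold).
#' @return integer vector of nucleotide indices.
#' @export
scaffoldOrder <- function(topology, strand = NULL) {
  if (is.null(strand)) strand <- which.max(tabulate(topology@strandId))
  idx <- which(topology@strandId == strand)
  start <- idx[is.na(topology@neighbor5[idx])]
  start <- if (length(start)) start[1] else min(idx)
  path <- integer(length(idx))
  cur <- start
  for (k in seq_along(idx)) {
    path[k] <- cur
    cur <- topology@neighbor3[cur]
    if (is.na(cur) || cur == start) break
  }
  if (k < length(idx)) stop("scaffoldOrder: strand neighbour links are not contiguous")
  path
}
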