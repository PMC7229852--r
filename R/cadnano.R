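#' @include AllClasses.R
NULL

.cnCell <- function(entry) as.integer(unlist(entry))

## walk one strand through the vstrand connectivity arrays starting from a
## (helix num, 0-based pos) cell; `field` is "scaf" or "stap"
.cnWalk <- function(vsByNum, field, helix, pos) {
  path <- matrix(NA_integer_, 0, 2)
  h <- helix; p <- pos
  start <- c(helix, pos)
  repeat {
    path <- rbind(path, c(h, p))
    cell <- .cnCell(vsByNum[[as.character(h)]][[field]][[p + 1L]])
    nh <- cell[3]; np <- cell[4]
    if (nh == -1L) break
    h <- nh; p <- np
    if (h == start[1] && p == start[2]) break  # circular strand closed
    if (nrow(path) > 1e6) stop("cadnano walk did not terminate")
  }
  colnames(path) <- c("helix", "pos")
  path
}

#' Read a cadnano design file (square lattice)
#'
#' Recovers scaffold routing, staple footprints, crossover positions and the
#' threaded scaffold sequence from a cadnano JSON (vstrands schema). Only the
#' square-lattice dialect is supported; 3D coordinates are not built here.
#'
#' @param path cadnano JSON path.
#' @param scaffoldSequence scaffold sequence, at least as long as the routed
#'   scaffold; threaded 5' to 3' along the path.
#' @param omitStaples integer indices (into the discovered staple list, ordered
#'   by 5' end helix/position) of staples omitted from assembly; their scaffold
#'   footprint is marked unpaired.
#' @return A [DesignMap-class].
#' @export
readCadnanoDesign <- function(path, scaffoldSequence, omitStaples = integer(0)) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  vs <- js$vstrands
  if (is.null(vs) || !length(vs)) stop("readCadnanoDesign: no vstrands in ", path)
  len <- length(vs[[1]]$scaf)
  if (len %% 32 != 0 && len %% 21 == 0)
    stop("readCadnanoDesign: honeycomb-lattice design (row length multiple of 21); ",
         "only square-lattice designs are supported")
  vsByNum <- stats::setNames(vs, vapply(vs, function(v) as.character(v$num), ""))

  occupied <- function(field) {
    cells <- matrix(NA_integer_, 0, 2)
    for (v in vs) {
      occ <- which(vapply(v[[field]], function(e) any(.cnCell(e) != -1L), logical(1)))
      if (length(occ)) cells <- rbind(cells, cbind(v$num, occ - 1L))
    }
    cells
  }
  scafCells <- occupied("scaf")
  if (!nrow(scafCells)) stop("readCadnanoDesign: empty scaffold")

  ## scaffold 5' end: prev == -1, next valid; circular scaffolds have none
  fiveEnd <- NULL
  for (v in vs) {
    for (p in seq_len(len) - 1L) {
      cell <- .cnCell(v$scaf[[p + 1L]])
      if (cell[1] == -1L && cell[3] != -1L) { fiveEnd <- c(v$num, p); break }
    }
    if (!is.null(fiveEnd)) break
  }
  if (is.null(fiveEnd)) fiveEnd <- scafCells[1, ]  # circular: start anywhere
  spath <- .cnWalk(vsByNum, "scaf", fiveEnd[1], fiveEnd[2])
  if (nrow(spath) < nrow(scafCells))
    stop(sprintf("readCadnanoDesign: disconnected scaffold path (%d of %d cells reached)",
                 nrow(spath), nrow(scafCells)))
  if (nchar(scaffoldSequence) < nrow(spath))
    stop(sprintf("readCadnanoDesign: scaffold sequence (%d nt) shorter than routing (%d nt)",
                 nchar(scaffoldSequence), nrow(spath)))
  seq <- toupper(substr(scaffoldSequence, 1, nrow(spath)))
  if (!grepl("^[ACGT]+$", seq)) stop("readCadnanoDesign: scaffold sequence must be ACGT")

  ## staples: walk from every 5' end
  staples <- list()
  for (v in vs) {
    for (p in seq_len(len) - 1L) {
      cell <- .cnCell(v$stap[[p + 1L]])
      if (cell[1] == -1L && cell[3] != -1L)
        staples[[length(staples) + 1L]] <- .cnWalk(vsByNum, "stap", v$num, p)
    }
  }
  if (length(staples) > 1) {
    ord <- order(vapply(staples, function(s) s[1, 1], 0L),
                 vapply(staples, function(s) s[1, 2], 0L))
    staples <- staples[ord]
  }
  omitStaples <- as.integer(omitStaples)
  if (any(omitStaples < 1 | omitStaples > length(staples)))
    stop("readCadnanoDesign: omitStaples out of range")

  xovers <- function(path, kind) {
    if (nrow(path) < 2) return(NULL)
    j <- which(path[-nrow(path), 1] != path[-1, 1])
    if (!length(j)) return(NULL)
    data.frame(helix = c(path[j, 1], path[j + 1, 1]),
               pos = c(path[j, 2], path[j + 1, 2]),
               partnerHelix = c(path[j + 1, 1], path[j, 1]),
               kind = kind, stringsAsFactors = FALSE)
  }
  cross <- do.call(rbind, c(list(xovers(spath, "scaffold")),
                            lapply(seq_along(staples), function(i) {
                              if (i %in% omitStaples) NULL
                              else xovers(staples[[i]], "staple")
                            })))
  if (is.null(cross))
    cross <- data.frame(helix = integer(0), pos = integer(0),
                        partnerHelix = integer(0), kind = character(0))

  ## paired mask along the scaffold path: covered by a non-omitted staple
  stapCells <- character(0)
  for (i in setdiff(seq_along(staples), omitStaples)) {
    s <- staples[[i]]
    stapCells <- c(stapCells, paste(s[, 1], s[, 2]))
  }
  paired <- paste(spath[, 1], spath[, 2]) %in% stapCells

  new("DesignMap",
      scaffoldPath = data.frame(helix = spath[, 1], pos = spath[, 2]),
      staples = lapply(staples, function(s) data.frame(helix = s[, 1], pos = s[, 2])),
      crossovers = cross, scaffoldSeq = seq, pairedMask = paired,
      omittedStaples = omitStaples)
}

#' Design-implied helical pitch
#'
#' Crossovers between one pair of adjacent helices recur at a fixed base-pair
#' spacing that the lattice equates to a whole number of helical turns
#' (square lattice: 32 bp for 3 turns). The pitch implied by the design is the
#' median junction spacing divided by the nearest integer number of turns at
#' the natural B-DNA pitch.
#'
#' @param design a [DesignMap-class].
#' @return pitch in bp per turn.
#' @export
designImpliedPitch <- function(design) {
  cr <- design@crossovers
  if (!nrow(cr)) stop("designImpliedPitch: design has no crossovers")
  pairKey <- paste(pmin(cr$helix, cr$partnerHelix), pmax(cr$helix, cr$partnerHelix))
  spacings <- unlist(lapply(split(cr$pos, pairKey), function(p) {
    p <- sort(unique(p))
    if (length(p) < 2) return(numeric(0))
    ## cluster adjacent positions (a double crossover spans neighbouring cells)
    cl <- cumsum(c(1, diff(p) > 2))
    centers <- tapply(p, cl, mean)
    if (length(centers) < 2) numeric(0) else diff(centers)
  }))
  if (!length(spacings)) stop("designImpliedPitch: fewer than two junctions per helix pair")
  s <- stats::median(spacings)
  turns <- max(1, round(s / 10.5))
  as.numeric(s / turns)
}
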