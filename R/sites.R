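#' @include AllClasses.R oxdna-io.R
NULL

#' Scan the scaffold for recognition-motif occurrences
#'
#' Finds every occurrence of `motif` on the scaffold sequence that lies in a
#' fully paired (duplex) region, including overlapping occurrences. Each site
#' gets a window of `windowSize` bp (`flankLeft` bp upstream of the motif plus
#' the balance downstream); windows reaching into unpaired or absent scaffold
#' are kept but flagged truncated. Site ids are 1-based in scaffold-path order.
#'
#' Scaffold path positions are mapped to topology nucleotide indices by the
#' 5' to 3' order of the topology's longest strand; staple partners come from
#' the topology pairing table (see [inferPairing()] when reading bare oxDNA
#' files).
#'
#' @param design a [DesignMap-class].
#' @param topology an [OxTopology-class] with a pairing table.
#' @param motif recognition sequence (ACGT, length >= 2; default GCGC).
#' @param flankLeft bp of upstream flank in the window (default 3).
#' @param windowSize docking window length in bp (default 10).
#' @param crossoverMargin bp margin used for crossover flagging (default 1).
#' @param substructures optional data.frame (start, end, label) of scaffold-path
#'   ranges labelling substructures.
#' @return list of [RecognitionSite-class] objects.
#' @export
scanRecognitionSites <- function(design, topology, motif = "GCGC",
                                 flankLeft = 3, windowSize = 10,
                                 crossoverMargin = 1, substructures = NULL) {
  motif <- toupper(motif)
  if (nchar(motif) < 2 || !grepl("^[ACGT]+$", motif))
    stop("scanRecognitionSites: motif must be ACGT of length >= 2")
  seq <- design@scaffoldSeq
  L <- nchar(seq)
  mlen <- nchar(motif)
  paired <- design@pairedMask
  scafOrd <- scaffoldOrder(topology)
  if (length(scafOrd) < L)
    stop("scanRecognitionSites: scaffold strand shorter than the design path")
  pairTab <- topology@pairing
  hasPairs <- length(pairTab) > 0

  starts <- which(vapply(seq_len(L - mlen + 1), function(k)
    substr(seq, k, k + mlen - 1) == motif, logical(1)))
  ## duplex regions only
  starts <- starts[vapply(starts, function(k) all(paired[k:(k + mlen - 1)]), logical(1))]

  sites <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    k <- starts[s]
    w0 <- k - flankLeft
    wpos <- seq(w0, w0 + windowSize - 1)
    inRange <- wpos >= 1 & wpos <= L
    winScaf <- rep(NA_integer_, windowSize)
    winScaf[inRange] <- scafOrd[wpos[inRange]]
    ## window bp falling on unpaired scaffold (by design) are truncated away
    winScaf[inRange][!paired[wpos[inRange]]] <- NA_integer_
    winStap <- rep(NA_integer_, windowSize)
    if (hasPairs) winStap[!is.na(winScaf)] <- pairTab[winScaf[!is.na(winScaf)]]
    truncated <- anyNA(winScaf) || anyNA(winStap)
    motifIdx <- scafOrd[k:(k + mlen - 1)]
    stapleIdx <- if (hasPairs) pairTab[motifIdx] else rep(NA_integer_, mlen)
    lab <- ""
    if (!is.null(substructures)) {
      hit <- which(substructures$start <= k & substructures$end >= k)
      if (length(hit)) lab <- substructures$label[hit[1]]
    }
    site <- new("RecognitionSite", id = s, motif = motif,
                scaffoldIdx = as.integer(motifIdx),
                stapleIdx = as.integer(stapleIdx),
                windowScaffoldIdx = as.integer(winScaf),
                windowStapleIdx = as.integer(winStap),
                pathStart = as.integer(k), truncated = truncated,
                crossoverOverlap = FALSE, substructure = lab)
    site@crossoverOverlap <- flagCrossoverOverlap(site, design, margin = crossoverMargin)
    sites[[s]] <- site
  }
  sites
}

#' Flag a site overlapping a crossover
#'
#' `TRUE` iff any base pair of the motif lies within `margin` bp of a scaffold
#' or staple crossover position on the same helix.
#'
#' @param site a [RecognitionSite-class].
#' @param design the [DesignMap-class] the site was scanned on.
#' @param margin bp margin (default 1).
#' @return logical(1).
#' @export
flagCrossoverOverlap <- function(site, design, margin = 1) {
  cr <- design@crossovers
  if (!nrow(cr)) return(FALSE)
  mlen <- nchar(site@motif)
  cells <- design@scaffoldPath[site@pathStart:(site@pathStart + mlen - 1), , drop = FALSE]
  any(vapply(seq_len(nrow(cells)), function(i)
    any(cr$helix == cells$helix[i] & abs(cr$pos - cells$pos[i]) <= margin),
    logical(1)))
}

#' Tabulate a site catalog
#'
#' @param sites list of [RecognitionSite-class] (from [scanRecognitionSites()]).
#' @return data.frame with one row per site (1-based inclusive path spans).
#' @export
siteTable <- function(sites) {
  do.call(rbind, lapply(sites, function(s) data.frame(
    id = s@id, motif = s@motif, pathStart = s@pathStart,
    pathEnd = s@pathStart + nchar(s@motif) - 1L,
    scaffoldStart = s@scaffoldIdx[1],
    scaffoldEnd = s@scaffoldIdx[length(s@scaffoldIdx)],
    truncated = s@truncated, crossoverOverlap = s@crossoverOverlap,
    substructure = s@substructure, stringsAsFactors = FALSE)))
}
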