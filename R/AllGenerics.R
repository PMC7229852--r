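#' @include AllClasses.R
NULL

#' Accessors for origamiAccess containers
#'
#' Small accessor generics: use these instead of reaching into slots.
#'
#' @param x an origamiAccess object.
#' @param ... unused.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nNucleotides", function(x) standardGeneric("nNucleotides"))
#' @rdname accessors
#' @export
setGeneric("nStrands", function(x) standardGeneric("nStrands"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x, ...) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("pairing", function(x) standardGeneric("pairing"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))
#' @rdname accessors
#' @export
setGeneric("meanStructure", function(x) standardGeneric("meanStructure"))
#' @rdname accessors
#' @export
setGeneric("totalMsf", function(x) standardGeneric("totalMsf"))
#' @rdname accessors
#' @export
setGeneric("selection", function(x) standardGeneric("selection"))
#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setMethod("nNucleotides", "OxTopology", function(x) x@nNucleotides)
#' @rdname accessors
#' @export
setMethod("nStrands", "OxTopology", function(x) x@nStrands)
#' @rdname accessors
#' @export
setMethod("pairing", "OxTopology", function(x) x@pairing)
#' @rdname accessors
#' @export
setMethod("nNucleotides", "OxTrajectory", function(x) x@topology@nNucleotides)
#' @rdname accessors
#' @export
setMethod("nFrames", "OxTrajectory", function(x) dim(x@positions)[3])
#' @rdname accessors
#' @export
setMethod("topology", "OxTrajectory", function(x) x@topology)
#' @rdname accessors
#' @export
setMethod("frameTimes", "OxTrajectory", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("positions", "OxConfiguration", function(x, ...) x@positions)
#' @rdname accessors
#' @export
setMethod("positions", "ParticleCloud", function(x, ...) x@positions)

#' @rdname accessors
#' @param i frame index.
#' @export
setMethod("getFrame", "OxTrajectory", function(x, i) {
  stopifnot(i >= 1, i <= nFrames(x))
  new("OxConfiguration",
      time = x@times[i], box = x@boxes[, i],
      positions = x@positions[, , i, drop = TRUE],
      bbVersor = x@bbVersors[, , i, drop = TRUE],
      normVersor = x@normVersors[, , i, drop = TRUE])
})

#' @rdname accessors
#' @export
setMethod("positions", "OxTrajectory", function(x, ...) x@positions)

#' @rdname accessors
#' @export
setMethod("eigenvalues", "ModeSpectrum", function(x) x@eigenvalues)
#' @rdname accessors
#' @export
setMethod("eigenvectors", "ModeSpectrum", function(x) x@eigenvectors)
#' @rdname accessors
#' @export
setMethod("meanStructure", "ModeSpectrum", function(x) x@meanStructure)
#' @rdname accessors
#' @export
setMethod("totalMsf", "ModeSpectrum", function(x) x@totalMsf)
#' @rdname accessors
#' @export
setMethod("selection", "ModeSpectrum", function(x) x@selection)
#' @rdname accessors
#' @export
setMethod("values", "ProjectionSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("frameTimes", "ProjectionSeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("fractions", "AccessibilityResult", function(x) x@fractions)

setMethod("show", "OxTopology", function(object) {
  cat(sprintf("OxTopology: %d nucleotides, %d strand(s)%s\n",
              object@nNucleotides, object@nStrands,
              if (length(object@pairing)) ", pairing table present" else ""))
})

setMethod("show", "OxTrajectory", function(object) {
  cat(sprintf("OxTrajectory: %d frames x %d nucleotides (lengthUnit %.4f nm)\n",
              nFrames(object), nNucleotides(object), object@lengthUnit))
})

setMethod("show", "ParticleCloud", function(object) {
  cat(sprintf("ParticleCloud (%s): %d particles\n", object@role, nrow(object@positions)))
})

setMethod("show", "ModeSpectrum", function(object) {
  k <- min(3L, length(object@eigenvalues))
  cat(sprintf("ModeSpectrum: N = %d nucleotides, %d modes; total MSF %.4g nm^2\n",
              length(object@selection), length(object@eigenvalues), object@totalMsf))
  cat("  leading eigenvalues (nm^2):", signif(object@eigenvalues[seq_len(k)], 4), "\n")
})

setMethod("show", "FEProfile", function(object) {
  cat(sprintf("FEProfile: %d bins (%d masked), barrierless range %.3g..%.3g nm\n",
              length(object@centers), sum(object@masked),
              min(object@centers), max(object@centers)))
})

setMethod("show", "TwoStateStats", function(object) {
  if (object@singleState) {
    cat("TwoStateStats: single state\n")
  } else {
    cat(sprintf(paste0("TwoStateStats: divider %.3g nm; populations %.3f/%.3f; ",
                       "barriers %.2f/%.2f kBT; %d transitions\n"),
                object@divider, object@populations[1], object@populations[2],
                object@barriers[1], object@barriers[2], object@transitions))
  }
})

setMethod("show", "RecognitionSite", function(object) {
  cat(sprintf("RecognitionSite %d (%s): path start %d%s%s\n",
              object@id, object@motif, object@pathStart,
              if (object@crossoverOverlap) ", crossover overlap" else "",
              if (object@truncated) ", truncated window" else ""))
})

setMethod("show", "DockingTemplate", function(object) {
  cat(sprintf("DockingTemplate: %d protein particles, %d bp helix, rmsd %.3g nm\n",
              nrow(object@protein@positions), object@helix@nBp, object@rmsd))
})

setMethod("show", "AccessibilityResult", function(object) {
  cat(sprintf("AccessibilityResult site %d: %s (frames used %d, skipped %d)\n",
              object@siteId,
              paste(sprintf("%s=%.3f", names(object@fractions), object@fractions),
                    collapse = ", "),
              object@framesUsed, object@framesSkipped))
})
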