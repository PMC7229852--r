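#' @include AllClasses.R rigid.R
NULL

## Coarse-grained geometry constants (nm). The nucleotide centre sits at a
## fixed radius from the duplex axis; the hydrogen-bonding (base) site lies on
## the axis and the backbone site slightly outward. Chosen so that the ideal
## duplex has an exact pseudo-dyad and paired hydrogen-bond sites coincide.
.cg <- list(
  radius = 0.6,        # nucleotide centre to axis
  baseOffset = 0.6,    # centre -> base site along +a1 (lands on the axis)
  backboneOffset = 0.2 # centre -> backbone site along -a1
)

#' Coarse-grained interaction centres of nucleotides
#'
#' Returns the backbone and base interaction sites implied by the nucleotide
#' centres and backbone-base versors: base site at `centre + baseOffset * a1`,
#' backbone site at `centre - backboneOffset * a1`.
#'
#' @param positions n x 3 nucleotide centres (nm).
#' @param bbVersor n x 3 unit backbone-base versors.
#' @param which "both", "base" or "backbone".
#' @return matrix of interaction-site coordinates (2n x 3 for "both").
#' @export
interactionCenters <- function(positions, bbVersor, which = c("both", "base", "backbone")) {
  which <- match.arg(which)
  base <- positions + .cg$baseOffset * bbVersor
  back <- positions - .cg$backboneOffset * bbVersor
  switch(which, both = rbind(back, base), base = base, backbone = back)
}

#' Build an ideal straight B-DNA duplex
#'
#' The axis runs along +z from the origin; strand 1 (5' to 3') advances with
#' the base-pair index, strand 2 is its antiparallel complement at opposite
#' azimuth. Base-pair centres lie exactly on the axis, separated by `rise`;
#' the azimuth advances by `twist` degrees per bp.
#'
#' @param nBp number of base pairs (>= 1).
#' @param sequence strand-1 sequence, length `nBp` (default poly-A).
#' @param rise axial rise per bp, nm (B-DNA default 0.34).
#' @param twist twist per bp, degrees (default 360/10.5).
#' @return A [HelixModel-class].
#' @examples
#' h <- buildIdealHelix(10)
#' @export
buildIdealHelix <- function(nBp, sequence = strrep("A", nBp),
                            rise = 0.34, twist = 360 / 10.5) {
  nBp <- as.integer(nBp)
  if (is.na(nBp) || nBp < 1) stop("buildIdealHelix: nBp must be >= 1")
  if (nchar(sequence) != nBp) stop("buildIdealHelix: sequence length must equal nBp")
  if (!grepl("^[ACGT]+$", sequence)) stop("buildIdealHelix: sequence must be ACGT")
  i <- seq_len(nBp) - 1
  phi <- i * twist * pi / 180
  z <- i * rise
  r <- .cg$radius
  s1 <- cbind(r * cos(phi), r * sin(phi), z)
  s2 <- cbind(-r * cos(phi), -r * sin(phi), z)
  a1s1 <- cbind(-cos(phi), -sin(phi), rep(0, nBp))   # points toward the axis
  a1s2 <- -a1s1
  a3s1 <- matrix(rep(c(0, 0, -1), each = nBp), nBp, 3)  # 3' -> 5' convention
  a3s2 <- -a3s1
  new("HelixModel",
      nBp = nBp, sequence = sequence, rise = rise, twist = twist,
      axisOrigin = c(0, 0, 0), axisDirection = c(0, 0, 1),
      strand1 = s1, strand2 = s2,
      bbVersor1 = a1s1, bbVersor2 = a1s2,
      normVersor1 = a3s1, normVersor2 = a3s2)
}

#' Base-pair centres of a helix model
#' @param helix a [HelixModel-class].
#' @return nBp x 3 matrix.
#' @export
helixBpCenters <- function(helix) (helix@strand1 + helix@strand2) / 2

#' Anchor points of a helix model for docking
#'
#' One anchor per nucleotide (the nucleotide centre), strand 1 rows first
#' (bp 1..n), then strand 2 rows (bp 1..n).
#'
#' @param helix a [HelixModel-class].
#' @return 2 nBp x 3 matrix.
#' @export
helixAnchors <- function(helix) rbind(helix@strand1, helix@strand2)

#' Local orthonormal frame of a recognition-site window
#'
#' The site axis is the principal direction of the window's base-pair centres,
#' oriented 5' to 3' along the scaffold strand; the origin is their centroid;
#' the in-plane reference direction is the component of the designated
#' nucleotide's backbone-base versor perpendicular to the axis.
#'
#' @param config an [OxConfiguration-class].
#' @param windowPairs k x 2 integer matrix of (scaffold, staple) nucleotide
#'   indices ordered 5' to 3' along the scaffold (k >= 3).
#' @param referenceNucleotide index of the nucleotide whose versor sets the
#'   reference direction.
#' @return A [LocalFrame-class].
#' @export
estimateSiteFrame <- function(config, windowPairs, referenceNucleotide) {
  windowPairs <- matrix(as.integer(windowPairs), ncol = 2)
  k <- nrow(windowPairs)
  if (k < 3) stop("estimateSiteFrame: window must span at least 3 bp")
  if (anyNA(windowPairs)) stop("estimateSiteFrame: window contains unpaired bp")
  ctr <- (config@positions[windowPairs[, 1], , drop = FALSE] +
          config@positions[windowPairs[, 2], , drop = FALSE]) / 2
  origin <- colMeans(ctr)
  X <- sweep(ctr, 2, origin)
  sv <- svd(X)
  if (sv$d[1] < 1e-9) stop("estimateSiteFrame: degenerate bp centres")
  axis <- sv$v[, 1]
  ## orient 5' -> 3' along the scaffold
  if (sum(axis * (ctr[k, ] - ctr[1, ])) < 0) axis <- -axis
  v <- config@bbVersor[referenceNucleotide, ]
  ref <- v - sum(v * axis) * axis
  nr <- sqrt(sum(ref^2))
  if (nr < 1e-9) stop("estimateSiteFrame: reference versor parallel to the axis")
  ref <- ref / nr
  third <- c(axis[2] * ref[3] - axis[3] * ref[2],
             axis[3] * ref[1] - axis[1] * ref[3],
             axis[1] * ref[2] - axis[2] * ref[1])
  new("LocalFrame", origin = origin, axis = axis, ref = ref, third = third)
}

#' Express points in a local frame
#'
#' @param frame a [LocalFrame-class].
#' @param points m x 3 matrix in lab coordinates.
#' @return m x 3 matrix of (axis, ref, third) coordinates.
#' @export
toLocalFrame <- function(frame, points) {
  B <- cbind(frame@axis, frame@ref, frame@third)
  sweep(points, 2, frame@origin) %*% B
}
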