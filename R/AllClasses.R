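#' @import methods
NULL

## Central S4 containers. All indices are 1-based; all lengths are in nm
## (oxDNA length units are converted at the file boundary).

#' Fixed strand topology of a coarse-grained DNA system
#'
#' Per-nucleotide strand membership, base identity, 3'/5' neighbour links and
#' (optionally) the design base-pairing table. Neighbour links use `NA` for a
#' strand terminus; pairing uses `NA` for unpaired nucleotides.
#'
#' @slot nNucleotides integer(1), number of nucleotides.
#' @slot nStrands integer(1), number of strands.
#' @slot strandId integer vector, strand membership per nucleotide.
#' @slot base character vector of bases (A/C/G/T).
#' @slot neighbor3 integer vector, index of the 3' neighbour or `NA`.
#' @slot neighbor5 integer vector, index of the 5' neighbour or `NA`.
#' @slot pairing integer vector (possibly length 0), complementary partner or `NA`.
#' @slot circular logical vector, one flag per strand.
#' @export
setClass("OxTopology", slots = c(
  nNucleotides = "integer",
  nStrands = "integer",
  strandId = "integer",
  base = "character",
  neighbor3 = "integer",
  neighbor5 = "integer",
  pairing = "integer",
  circular = "logical"
))

setValidity("OxTopology", function(object) {
  n <- object@nNucleotides
  msg <- character()
  if (length(object@strandId) != n || length(object@base) != n ||
      length(object@neighbor3) != n || length(object@neighbor5) != n)
    msg <- c(msg, "per-nucleotide slots must have length nNucleotides")
  if (!all(object@base %in% c("A", "C", "G", "T")))
    msg <- c(msg, "bases must be A/C/G/T")
  ## mutual neighbour links: i's 3' neighbour must have i as its 5' neighbour
  has3 <- which(!is.na(object@neighbor3))
  if (length(has3) && !all(object@neighbor5[object@neighbor3[has3]] == has3, na.rm = FALSE))
    msg <- c(msg, "3'/5' neighbour links are not mutual")
  has5 <- which(!is.na(object@neighbor5))
  if (length(has5) && !all(object@neighbor3[object@neighbor5[has5]] == has5, na.rm = FALSE))
    msg <- c(msg, "5'/3' neighbour links are not mutual")
  if (length(object@pairing)) {
    if (length(object@pairing) != n) {
      msg <- c(msg, "pairing must have length nNucleotides (or 0)")
    } else {
      p <- which(!is.na(object@pairing))
      if (length(p) && !all(object@pairing[object@pairing[p]] == p))
        msg <- c(msg, "pairing is not an involution")
      comp <- c(A = "T", T = "A", C = "G", G = "C")
      if (length(p) && !all(object@base[object@pairing[p]] == comp[object@base[p]]))
        msg <- c(msg, "paired bases are not complementary")
    }
  }
  if (length(object@circular) != object@nStrands)
    msg <- c(msg, "circular must have one flag per strand")
  if (length(msg)) msg else TRUE
})

#' A single trajectory frame
#'
#' @slot time numeric(1), simulation time (microseconds).
#' @slot box numeric(3), box edge lengths (nm).
#' @slot positions n x 3 matrix of nucleotide centres (nm).
#' @slot bbVersor n x 3 matrix, unit backbone-base versors.
#' @slot normVersor n x 3 matrix, unit base-normal versors.
#' @export
setClass("OxConfiguration", slots = c(
  time = "numeric",
  box = "numeric",
  positions = "matrix",
  bbVersor = "matrix",
  normVersor = "matrix"
))

setValidity("OxConfiguration", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (ncol(object@positions) != 3) msg <- c(msg, "positions must be n x 3")
  for (nm in c("bbVersor", "normVersor")) {
    v <- slot(object, nm)
    if (!all(dim(v) == c(n, 3))) {
      msg <- c(msg, sprintf("%s must match positions in shape", nm))
    } else if (n > 0 && max(abs(sqrt(rowSums(v^2)) - 1)) > 1e-6) {
      msg <- c(msg, sprintf("%s rows must be unit vectors (1e-6)", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' An ordered set of frames sharing one topology
#'
#' Coordinates are stored as dense arrays of shape `n x 3 x T`.
#'
#' @slot topology an [OxTopology-class].
#' @slot positions numeric array n x 3 x T (nm).
#' @slot bbVersors numeric array n x 3 x T.
#' @slot normVersors numeric array n x 3 x T.
#' @slot times numeric(T), strictly increasing (microseconds).
#' @slot boxes 3 x T matrix (nm).
#' @slot lengthUnit numeric(1), nm per oxDNA length unit already applied.
#' @export
setClass("OxTrajectory", slots = c(
  topology = "OxTopology",
  positions = "array",
  bbVersors = "array",
  normVersors = "array",
  times = "numeric",
  boxes = "matrix",
  lengthUnit = "numeric"
))

setValidity("OxTrajectory", function(object) {
  msg <- character()
  d <- dim(object@positions)
  if (length(d) != 3 || d[2] != 3) msg <- c(msg, "positions must be n x 3 x T")
  if (d[1] != object@topology@nNucleotides)
    msg <- c(msg, "frame size does not match topology")
  if (length(object@times) != d[3]) msg <- c(msg, "times must match frame count")
  if (d[3] > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' A labelled point cloud (protein or DNA particles)
#'
#' @slot positions m x 3 matrix (nm).
#' @slot labels data.frame with columns chain, resid, atom.
#' @slot role character(1), "protein" or "dna".
#' @export
setClass("ParticleCloud", slots = c(
  positions = "matrix",
  labels = "data.frame",
  role = "character"
))

setValidity("ParticleCloud", function(object) {
  msg <- character()
  if (nrow(object@positions) == 0) msg <- c(msg, "cloud must be nonempty")
  if (!all(is.finite(object@positions))) msg <- c(msg, "coordinates must be finite")
  if (!object@role %in% c("protein", "dna")) msg <- c(msg, "role must be protein or dna")
  if (nrow(object@labels) != nrow(object@positions))
    msg <- c(msg, "labels must have one row per particle")
  if (length(msg)) msg else TRUE
})

#' Routing and crossover annotation of a cadnano design
#'
#' @slot scaffoldPath data.frame (helix, pos), ordered 5' to 3'.
#' @slot staples list of data.frames (helix, pos), each ordered 5' to 3'.
#' @slot crossovers data.frame (helix, pos, kind) with kind scaffold/staple.
#' @slot scaffoldSeq character(1), sequence threaded along the path.
#' @slot pairedMask logical along the scaffold path (paired by a staple).
#' @slot omittedStaples integer indices into the staple list.
#' @export
setClass("DesignMap", slots = c(
  scaffoldPath = "data.frame",
  staples = "list",
  crossovers = "data.frame",
  scaffoldSeq = "character",
  pairedMask = "logical",
  omittedStaples = "integer"
))

#' A proper rigid-body motion
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3) (nm).
#' @export
setClass("RigidTransform", slots = c(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-10) msg <- c(msg, "rotation not orthonormal")
    if (abs(det(R) - 1) > 1e-10) msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (length(object@translation) != 3) msg <- c(msg, "translation must be length 3")
  if (length(msg)) msg else TRUE
})

#' Ideal straight B-DNA duplex in the coarse-grained representation
#'
#' Strand 1 runs 5' to 3' with base-pair index; strand 2 is its antiparallel
#' complement (its own 5' to 3' order is bp n..1). The model owns an exact
#' pseudo-dyad: a 180 degree rotation about an in-plane axis maps strand 1
#' onto strand 2 with the base-pair order reversed.
#'
#' @slot nBp integer(1).
#' @slot sequence character(1), strand-1 sequence.
#' @slot rise numeric(1) nm per bp.
#' @slot twist numeric(1) degrees per bp.
#' @slot axisOrigin numeric(3).
#' @slot axisDirection unit numeric(3).
#' @slot strand1,strand2 n x 3 nucleotide-centre matrices (nm).
#' @slot bbVersor1,bbVersor2 n x 3 unit versors.
#' @slot normVersor1,normVersor2 n x 3 unit versors.
#' @export
setClass("HelixModel", slots = c(
  nBp = "integer", sequence = "character", rise = "numeric", twist = "numeric",
  axisOrigin = "numeric", axisDirection = "numeric",
  strand1 = "matrix", strand2 = "matrix",
  bbVersor1 = "matrix", bbVersor2 = "matrix",
  normVersor1 = "matrix", normVersor2 = "matrix"
))

#' Right-handed orthonormal frame attached to a recognition site
#'
#' @slot origin numeric(3), centroid of the window bp centres (nm).
#' @slot axis unit numeric(3), site helical axis oriented 5' to 3' (scaffold).
#' @slot ref unit numeric(3), in-plane reference direction.
#' @slot third unit numeric(3), axis x ref.
#' @export
setClass("LocalFrame", slots = c(
  origin = "numeric", axis = "numeric", ref = "numeric", third = "numeric"
))

setValidity("LocalFrame", function(object) {
  B <- cbind(object@axis, object@ref, object@third)
  if (max(abs(crossprod(B) - diag(3))) > 1e-9) "frame triad not orthonormal (1e-9)"
  else TRUE
})

#' Eigenmodes of the positional covariance of a selection
#'
#' @slot selection integer nucleotide indices (N particles).
#' @slot meanStructure numeric(3N), trajectory mean (nm), layout x1,y1,z1,x2,...
#' @slot eigenvalues numeric, nonnegative, descending (nm^2).
#' @slot eigenvectors 3N x k orthonormal columns.
#' @slot totalMsf numeric(1), sum of all eigenvalues (nm^2).
#' @export
setClass("ModeSpectrum", slots = c(
  selection = "integer", meanStructure = "numeric",
  eigenvalues = "numeric", eigenvectors = "matrix", totalMsf = "numeric"
))

setValidity("ModeSpectrum", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (any(ev < -1e-10)) msg <- c(msg, "eigenvalues must be nonnegative")
  if (is.unsorted(rev(ev), strictly = FALSE)) msg <- c(msg, "eigenvalues must be descending")
  V <- object@eigenvectors
  if (nrow(V) != 3L * length(object@selection))
    msg <- c(msg, "eigenvectors must have 3N rows")
  if (ncol(V) && max(abs(crossprod(V) - diag(ncol(V)))) > 1e-8)
    msg <- c(msg, "eigenvectors must be orthonormal (1e-8)")
  if (length(msg)) msg else TRUE
})

#' Scalar projection of a trajectory onto one mode
#'
#' @slot values numeric(T), projections (nm).
#' @slot times numeric(T).
#' @slot modeId character(1).
#' @export
setClass("ProjectionSeries", slots = c(
  values = "numeric", times = "numeric", modeId = "character"
))

#' Free-energy profile by Boltzmann inversion of a 1D histogram
#'
#' @slot centers bin centres (nm).
#' @slot free free energy (kBT), min 0; `NA` in masked bins.
#' @slot counts integer counts per bin.
#' @slot masked logical, zero-count bins.
#' @export
setClass("FEProfile", slots = c(
  centers = "numeric", free = "numeric", counts = "integer", masked = "logical"
))

setValidity("FEProfile", function(object) {
  msg <- character()
  if (any(object@free < -1e-12, na.rm = TRUE)) msg <- c(msg, "free energy must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Two-state statistics of a projection series
#'
#' @slot singleState logical(1).
#' @slot divider numeric(1), position of the barrier top (nm); `NA` if single state.
#' @slot populations numeric, per-state fractions (low side first).
#' @slot residence numeric, mean run length per state (frames).
#' @slot transitions integer(1), divider crossings.
#' @slot barriers numeric, barrier height from each minimum (kBT).
#' @export
setClass("TwoStateStats", slots = c(
  singleState = "logical", divider = "numeric", populations = "numeric",
  residence = "numeric", transitions = "integer", barriers = "numeric"
))

#' A recognition-motif occurrence on the scaffold strand
#'
#' @slot id integer(1), 1-based rank along the scaffold path.
#' @slot motif character(1).
#' @slot scaffoldIdx integer, topology indices of the motif, 5' to 3'.
#' @slot stapleIdx integer, paired partners of `scaffoldIdx`.
#' @slot windowScaffoldIdx integer(10), window scaffold indices (`NA` if truncated).
#' @slot windowStapleIdx integer(10), window staple indices (`NA` if unpaired).
#' @slot pathStart integer(1), motif start along the scaffold path.
#' @slot truncated logical(1), window extends into unpaired/absent scaffold.
#' @slot crossoverOverlap logical(1).
#' @slot substructure character(1), optional label ("" if none).
#' @export
setClass("RecognitionSite", slots = c(
  id = "integer", motif = "character",
  scaffoldIdx = "integer", stapleIdx = "integer",
  windowScaffoldIdx = "integer", windowStapleIdx = "integer",
  pathStart = "integer", truncated = "logical",
  crossoverOverlap = "logical", substructure = "character"
))

#' Enzyme particles expressed in the ideal-helix frame
#'
#' @slot protein a [ParticleCloud-class] in the helix frame.
#' @slot helix the [HelixModel-class] used for anchoring.
#' @slot correspondence data.frame mapping crystal nucleotides to helix slots.
#' @slot rmsd numeric(1), superposition rmsd of the crystal duplex (nm).
#' @slot engagedStrand character(1), helix strand the enzyme contacts ("strand1").
#' @export
setClass("DockingTemplate", slots = c(
  protein = "ParticleCloud", helix = "HelixModel",
  correspondence = "data.frame", rmsd = "numeric", engagedStrand = "character"
))

#' Max/min distance maps on the (base pair, azimuth) grid
#'
#' @slot maxMap nBp x nTheta matrix, farthest protein particle per cell (-Inf empty).
#' @slot minMap nBp x nTheta matrix, nearest environment particle per cell (+Inf empty).
#' @slot thetaBreaks numeric(nTheta + 1) bin edges over (-pi, pi].
#' @export
setClass("DistanceMaps", slots = c(
  maxMap = "matrix", minMap = "matrix", thetaBreaks = "numeric"
))

setValidity("DistanceMaps", function(object) {
  msg <- character()
  if (!all(dim(object@maxMap) == dim(object@minMap)))
    msg <- c(msg, "max and min maps must share a grid")
  if (any(object@maxMap[is.finite(object@maxMap)] < 0))
    msg <- c(msg, "populated max cells must be >= 0")
  if (any(object@minMap[is.finite(object@minMap)] <= 0))
    msg <- c(msg, "populated min cells must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-frame and aggregated accessibility of one site
#'
#' @slot siteId integer(1).
#' @slot perFrame logical matrix, frames x sides (NA where the frame was skipped).
#' @slot fractions named numeric, per-side fractions plus "both".
#' @slot framesUsed integer(1).
#' @slot framesSkipped integer(1).
#' @export
setClass("AccessibilityResult", slots = c(
  siteId = "integer", perFrame = "matrix", fractions = "numeric",
  framesUsed = "integer", framesSkipped = "integer"
))

#' In-plane occupancy of the neighbourhood of a site
#'
#' @slot siteId integer(1).
#' @slot neighbors named list of T x 2 matrices: per-frame projected neighbour
#'   centres of mass in the site frame (nm).
#' @slot footprint named list (per side) of 2-column convex-hull vertices of
#'   the projected enzyme.
#' @export
setClass("LocalOccupancy", slots = c(
  siteId = "integer", neighbors = "list", footprint = "list"
))
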