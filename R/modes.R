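#' @include AllClasses.R rigid.R
NULL

## 3N vector layout used throughout: (x1, y1, z1, x2, y2, z2, ...)
.flatten <- function(mat) as.vector(t(mat))
.unflatten <- function(vec) matrix(vec, ncol = 3, byrow = TRUE)

#' Align a trajectory onto its first frame and compute mean and RMSF
#'
#' Every frame is rigidly superposed (Kabsch, uniform weights) onto the first
#' frame over the given selection; the transform is applied to all nucleotides
#' and versors. The mean structure is the single-pass average of the aligned
#' selection and RMSF_i = sqrt(<|r_i(t) - <r_i>|^2>).
#'
#' @param traj an [OxTrajectory-class] with >= 2 frames.
#' @param selection integer nucleotide indices used for the fit (nonempty).
#' @return list with `aligned` (an [OxTrajectory-class]), `mean` (N x 3 matrix
#'   over the selection, nm) and `rmsf` (numeric N, nm).
#' @export
alignAndAverage <- function(traj, selection) {
  selection <- as.integer(selection)
  if (!length(selection)) stop("alignAndAverage: empty selection")
  tt <- nFrames(traj)
  if (tt < 2) stop("alignAndAverage: need at least 2 frames")
  ref <- traj@positions[selection, , 1, drop = FALSE]
  dim(ref) <- c(length(selection), 3)
  pos <- traj@positions
  bb <- traj@bbVersors
  nv <- traj@normVersors
  for (t in seq_len(tt)) {
    fr <- pos[, , t]
    fit <- kabschSuperpose(fr[selection, , drop = FALSE], ref)
    pos[, , t] <- applyTransform(fit$transform, fr)
    bb[, , t] <- applyTransform(fit$transform, bb[, , t], rotateOnly = TRUE)
    nv[, , t] <- applyTransform(fit$transform, nv[, , t], rotateOnly = TRUE)
  }
  aligned <- traj
  aligned@positions <- pos
  aligned@bbVersors <- bb
  aligned@normVersors <- nv
  sel <- pos[selection, , , drop = FALSE]
  meanStruct <- apply(sel, c(1, 2), mean)
  dev2 <- (sel - array(meanStruct, dim(sel)))^2
  rmsf <- sqrt(apply(dev2, 1, sum) / tt)
  list(aligned = aligned, mean = meanStruct, rmsf = rmsf)
}

#' Positional covariance eigenmodes of an aligned trajectory
#'
#' Assembles per-frame 3N deviation vectors from the trajectory mean over the
#' selection, forms the covariance C = (1/T) sum_t x(t) x(t)^T and returns its
#' full eigendecomposition. Eigenvector signs are fixed so the
#' largest-magnitude component of each mode is positive.
#'
#' @param traj an aligned [OxTrajectory-class] (see [alignAndAverage()]).
#' @param selection integer nucleotide indices (N).
#' @return A [ModeSpectrum-class].
#' @export
covarianceModes <- function(traj, selection) {
  selection <- as.integer(selection)
  tt <- nFrames(traj)
  if (tt < 2) stop("covarianceModes: need at least 2 frames")
  N <- length(selection)
  D <- matrix(0, tt, 3 * N)
  for (t in seq_len(tt)) D[t, ] <- .flatten(traj@positions[selection, , t])
  mu <- colMeans(D)
  D <- sweep(D, 2, mu)
  C <- crossprod(D) / tt
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  ## sign convention: largest-|component| positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  new("ModeSpectrum", selection = selection, meanStructure = mu,
      eigenvalues = ev, eigenvectors = V, totalMsf = sum(ev))
}

#' Collinearity of two mode spectra
#'
#' Matrix of absolute inner products |<p_i^A | p_j^B>| between the first `k`
#' eigenvectors of two spectra computed on identical selections.
#'
#' @param spectrumA,spectrumB [ModeSpectrum-class] objects on the same selection.
#' @param k number of leading modes to compare.
#' @return k x k matrix with entries in `[0, 1]`.
#' @export
collinearityMatrix <- function(spectrumA, spectrumB, k = 10) {
  if (length(spectrumA@selection) != length(spectrumB@selection) ||
      any(spectrumA@selection != spectrumB@selection))
    stop("collinearityMatrix: spectra must share one selection")
  k <- min(k, ncol(spectrumA@eigenvectors), ncol(spectrumB@eigenvectors))
  abs(crossprod(spectrumA@eigenvectors[, seq_len(k), drop = FALSE],
                spectrumB@eigenvectors[, seq_len(k), drop = FALSE]))
}

#' Project an aligned trajectory onto one mode
#'
#' s_t = <x_t - center | mode> with x_t the flattened selection coordinates.
#' When the mode comes from a different structure, `indexMap` must give, for
#' each nucleotide slot of the mode's selection, the corresponding nucleotide
#' index of `traj` (no automatic matching is attempted).
#'
#' @param traj an aligned [OxTrajectory-class].
#' @param spectrum a [ModeSpectrum-class] providing mode and centre.
#' @param mode mode number (column of the spectrum), default 1.
#' @param indexMap optional integer vector, length N of the spectrum selection.
#' @param modeId label stored on the series.
#' @return A [ProjectionSeries-class].
#' @export
projectOntoMode <- function(traj, spectrum, mode = 1, indexMap = NULL,
                            modeId = sprintf("p%d", mode)) {
  N <- length(spectrum@selection)
  sel <- if (is.null(indexMap)) spectrum@selection else as.integer(indexMap)
  if (length(sel) != N)
    stop("projectOntoMode: index mapping must cover the mode's selection")
  if (max(sel) > nNucleotides(traj))
    stop("projectOntoMode: index mapping outside trajectory")
  p <- spectrum@eigenvectors[, mode]
  ctr <- spectrum@meanStructure
  tt <- nFrames(traj)
  s <- numeric(tt)
  for (t in seq_len(tt))
    s[t] <- sum((.flatten(traj@positions[sel, , t]) - ctr) * p)
  new("ProjectionSeries", values = s, times = traj@times, modeId = modeId)
}
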