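#' @include AllClasses.R
NULL

#' Free-energy profile by Boltzmann inversion
#'
#' Histograms the projection series over its range and inverts the density:
#' F(bin) = -ln(count/total) in units of kBT, offset so the minimum is zero.
#' Zero-count bins are masked (`NA`), never interpolated.
#'
#' @param series a [ProjectionSeries-class] (or numeric vector).
#' @param nBins number of bins (>= 5; default 100).
#' @return A [FEProfile-class].
#' @export
freeEnergyProfile <- function(series, nBins = 100) {
  x <- if (is(series, "ProjectionSeries")) series@values else as.numeric(series)
  if (nBins < 5) stop("freeEnergyProfile: need at least 5 bins")
  rng <- range(x)
  if (diff(rng) == 0) stop("freeEnergyProfile: degenerate histogram (all samples identical)")
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1)
  counts <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE), nBins),
                     nbins = nBins)
  free <- -log(counts / length(x))
  masked <- counts == 0
  free[masked] <- NA_real_
  free <- free - min(free, na.rm = TRUE)
  new("FEProfile", centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
      free = free, counts = as.integer(counts), masked = masked)
}

## locate the two wells of a profile; returns NULL when no second well has a
## separating barrier of at least minBarrier kBT
.findWells <- function(profile, minBarrier, minSeparation = 2L) {
  F <- profile@free
  valid <- which(!profile@masked)
  if (length(valid) < 3) return(NULL)
  m1 <- valid[which.min(F[valid])]
  best <- NULL
  for (j in valid) {
    if (abs(j - m1) < minSeparation) next
    between <- valid[valid > min(j, m1) & valid < max(j, m1)]
    if (!length(between)) next
    top <- between[which.max(F[between])]
    if (F[top] - F[j] >= minBarrier && F[top] - F[m1] >= minBarrier) {
      if (is.null(best) || F[j] < F[best$m2]) best <- list(m2 = j, top = top)
    }
  }
  if (is.null(best)) return(NULL)
  lo <- min(m1, best$m2); hi <- max(m1, best$m2)
  between <- valid[valid > lo & valid < hi]
  top <- between[which.max(F[between])]
  list(minima = sort(c(m1, best$m2)), divider = top)
}

#' Two-state statistics of a projection series
#'
#' Locates the two free-energy wells (requiring a separating barrier of at
#' least `minBarrier` kBT and >= 2 bins between the minima), places the state
#' divider at the barrier top, labels frames by side, and reports populations,
#' mean residence times, transition counts and barrier heights. With no second
#' well a single-state result is returned.
#'
#' @param series a [ProjectionSeries-class].
#' @param profile the matching [FEProfile-class].
#' @param minBarrier minimum separating barrier (kBT) for a well to count
#'   (default 0.5).
#' @return A [TwoStateStats-class].
#' @export
twoStateStats <- function(series, profile, minBarrier = 0.5) {
  wells <- .findWells(profile, minBarrier)
  if (is.null(wells)) {
    return(new("TwoStateStats", singleState = TRUE, divider = NA_real_,
               populations = 1, residence = as.numeric(length(series@values)),
               transitions = 0L, barriers = numeric(0)))
  }
  F <- profile@free
  divider <- profile@centers[wells$divider]
  labels <- series@values > divider
  runs <- rle(labels)
  pops <- c(mean(!labels), mean(labels))
  res <- c(mean(runs$lengths[!runs$values]), mean(runs$lengths[runs$values]))
  res[is.nan(res)] <- 0
  new("TwoStateStats", singleState = FALSE, divider = divider,
      populations = pops, residence = res,
      transitions = length(runs$lengths) - 1L,
      barriers = F[wells$divider] - F[wells$minima])
}

#' Synchronization of two projection series
#'
#' State-label agreement and Pearson correlation of two equally long series.
#'
#' @param seriesA,seriesB [ProjectionSeries-class] objects of equal length.
#' @param dividers numeric(2), state divider for each series (nm).
#' @return list with `agreement` (fraction of frames with equal state labels)
#'   and `correlation` (Pearson, on the raw values).
#' @export
synchronization <- function(seriesA, seriesB, dividers) {
  a <- seriesA@values; b <- seriesB@values
  if (length(a) != length(b)) stop("synchronization: series length mismatch")
  la <- a > dividers[1]; lb <- b > dividers[2]
  list(agreement = mean(la == lb), correlation = stats::cor(a, b))
}
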