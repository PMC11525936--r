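# Automatic histogram thresholds used across the pipeline.

#' Multi-level Otsu thresholds
#'
#' Exhaustive-search multi-class Otsu on a fixed-bin histogram: the returned
#' cut points maximize the between-class variance of the resulting classes.
#' With `classes = 3` (the default used for DAPI/EPCAM preprocessing) two
#' thresholds are returned.
#'
#' @param x numeric vector or matrix of intensities.
#' @param classes number of classes (2 or 3).
#' @param nbins number of histogram bins.
#' @return numeric vector of `classes - 1` thresholds on the data scale.
#' @export
multiotsu_thresholds <- function(x, classes = 3, nbins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  assert_that(rng[1] < rng[2], "constant input: no dynamic range to threshold")
  assert_that(classes %in% c(2, 3), "classes must be 2 or 3")
  # histogram over [min, max]; bin centres carry the data scale
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nbins), nbins)
  centres <- (br[-1] + br[-(nbins + 1)]) / 2
  p <- h / sum(h)
  cw <- cumsum(p)                 # class weight prefix
  cm <- cumsum(p * centres)       # class mean-mass prefix
  wsum <- function(a, b) cw[b] - if (a > 1) cw[a - 1] else 0
  msum <- function(a, b) cm[b] - if (a > 1) cm[a - 1] else 0
  score2 <- function(t1) {
    w1 <- wsum(1, t1); w2 <- wsum(t1 + 1, nbins)
    s <- 0
    if (w1 > 0) s <- s + msum(1, t1)^2 / w1
    if (w2 > 0) s <- s + msum(t1 + 1, nbins)^2 / w2
    s
  }
  # thresholds are reported as upper bin edges, so that every value binned
  # at or below the cut bin satisfies x <= threshold exactly
  if (classes == 2) {
    sc <- vapply(seq_len(nbins - 1), score2, numeric(1))
    return(br[which.max(sc) + 1])
  }
  best <- -Inf; bt <- c(1L, 2L)
  for (t1 in seq_len(nbins - 2)) {
    w1 <- wsum(1, t1)
    s1 <- if (w1 > 0) msum(1, t1)^2 / w1 else 0
    for (t2 in (t1 + 1):(nbins - 1)) {
      w2 <- wsum(t1 + 1, t2); w3 <- wsum(t2 + 1, nbins)
      s <- s1 +
        (if (w2 > 0) msum(t1 + 1, t2)^2 / w2 else 0) +
        (if (w3 > 0) msum(t2 + 1, nbins)^2 / w3 else 0)
      if (s > best) { best <- s; bt <- c(t1, t2) }
    }
  }
  br[bt + 1]
}

#' Triangle threshold
#'
#' Geometric (Zack) threshold on a fixed-bin histogram: a line is drawn from
#' the histogram peak to the far end of the longer tail, and the threshold is
#' the bin maximizing the perpendicular distance to that line.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins.
#' @return a single threshold on the data scale.
#' @export
triangle_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  assert_that(rng[1] < rng[2], "constant input: no dynamic range to threshold")
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nbins), nbins)
  centres <- (br[-1] + br[-(nbins + 1)]) / 2
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # work on the longer tail; mirror so the tail is to the right of the peak
  flipped <- (peak - lo) > (hi - peak)
  if (flipped) { h <- rev(h); peak <- nbins - peak + 1; hi <- nbins - lo + 1 }
  if (hi <= peak) return(centres[if (flipped) nbins - peak + 1 else peak])
  idx <- peak:hi
  # signed distance (up to a positive factor) from (i, h_i) to the line
  # through (peak, h_peak) and (hi, h_hi); zero at both endpoints
  dist <- (hi - peak) * (h[peak] - h[idx]) - (h[peak] - h[hi]) * (idx - peak)
  t_bin <- idx[which.max(dist)]
  if (flipped) t_bin <- nbins - t_bin + 1
  centres[t_bin]
}
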