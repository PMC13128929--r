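#' Automatic global intensity thresholds
#'
#' Histogram-based global thresholds used throughout the imaging pipeline:
#' IsoData (ridler-calvard iterative intermeans, used for DAPI nuclei), Yen's
#' maximum-correlation criterion (used for TUNEL puncta) and Otsu (used for
#' vessel/positive-area masks, via \pkg{EBImage}). All operate on the raw
#' intensity values of a single channel; a pixel is called positive when its
#' intensity is strictly greater than the returned threshold.
#'
#' @param x numeric matrix (or vector) of intensities.
#' @param n_bins number of histogram bins for the Yen criterion.
#' @return a single numeric threshold on the intensity scale of `x`.
#' @name thresholds
NULL

#' @rdname thresholds
#' @export
threshold_isodata <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0 || diff(range(v)) == 0) return(max(v, 0))
  t_old <- -Inf
  t_new <- mean(v)
  for (i in seq_len(200)) {
    lo <- v[v <= t_new]
    hi <- v[v > t_new]
    if (length(lo) == 0 || length(hi) == 0) break
    t_old <- t_new
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_old) < 1e-10 * diff(range(v))) break
  }
  t_new
}

#' @rdname thresholds
#' @export
threshold_yen <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0 || diff(range(v)) == 0) return(max(v, 0))
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- h / sum(h)
  P1 <- cumsum(p)
  S1 <- cumsum(p^2)
  S2 <- sum(p^2) - S1
  # Yen's maximum-correlation criterion; guard empty-side candidates
  valid <- P1 > 0 & P1 < 1 & S1 > 0 & S2 > 0
  if (!any(valid)) return(mean(rng))
  crit <- rep(-Inf, n_bins)
  crit[valid] <- -log(S1[valid] * S2[valid]) +
    2 * log(P1[valid] * (1 - P1[valid]))
  k <- which.max(crit)
  # threshold at the upper edge of the selected bin: positives are > thr
  breaks[k + 1L]
}

#' @rdname thresholds
#' @export
threshold_otsu <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0 || diff(range(v)) == 0) return(max(v, 0))
  rng <- range(v)
  m <- matrix(v, ncol = 1)
  EBImage::otsu(EBImage::Image(m), range = rng, levels = 256L)
}

# Dispatch on a method name kept in QuantParams.
auto_threshold <- function(x, method = c("otsu", "isodata", "yen")) {
  method <- match.arg(method)
  switch(method,
    otsu = threshold_otsu(x),
    isodata = threshold_isodata(x),
    yen = threshold_yen(x)
  )
}
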