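# Undecimated (à trous) dyadic wavelet transform with the quadratic-spline
# derivative-of-smoothing wavelet — the classical ECG delineation transform.
# Coefficients at each scale approximate the derivative of a smoothed copy of
# the signal, so a wave peak shows up as a positive/negative modulus-extremum
# pair whose zero crossing marks the peak.

SPLINE_H <- c(1, 3, 3, 1) / 8 # lowpass, group delay 1.5 samples
SPLINE_G <- c(2, -2)          # highpass (first difference), delay 0.5

upsample_filter <- function(f, m) {
  if (m == 1) {
    return(f)
  }
  out <- numeric((length(f) - 1L) * m + 1L)
  out[seq(1L, length(out), by = m)] <- f
  out
}

# equivalent filter and (0-based, possibly half-integer) center per scale
equivalent_filters <- function(scales) {
  filt <- vector("list", scales)
  smooth <- 1
  for (j in seq_len(scales)) {
    m <- 2^(j - 1L)
    qj <- convolve(upsample_filter(SPLINE_G, m), rev(smooth), type = "open")
    filt[[j]] <- list(q = qj, center = 2^j - 1.5)
    smooth <- convolve(upsample_filter(SPLINE_H, m), rev(smooth), type = "open")
  }
  filt
}

#' Dyadic wavelet transform of one ECG lead
#'
#' Translation-invariant quadratic-spline wavelet transform at scales
#' `2^1 ... 2^scales`, with symmetric border extension.  The transform is
#' linear and annihilates constants; the half-sample group delay of the
#' spline filters is removed by averaging the two neighbouring integer
#' shifts, so the output is zero-phase.
#'
#' @param x numeric vector, one lead.
#' @param scales maximum dyadic scale index J (coefficients are returned for
#'   scales `1..J`, i.e. widths `2^1..2^J`).
#' @return object of class `ecg_wavelet`: list with `w` (list of J
#'   coefficient vectors, each `length(x)` long) and `n`.
#' @examples
#' w <- ecg_wavelet(sin(seq(0, 10, length.out = 500)), scales = 4)
#' length(w$w[[4]])
#' @export
ecg_wavelet <- function(x, scales = 5L) {
  x <- as.numeric(x)
  n <- length(x)
  filt <- equivalent_filters(scales)
  lmax <- length(filt[[scales]]$q)
  if (n < lmax) {
    abort(sprintf("Signal too short: need at least %d samples for scale %d.", lmax, scales))
  }
  pad <- lmax
  xp <- c(x[pad:1], x, x[n:(n - pad + 1L)]) # symmetric extension
  w <- vector("list", scales)
  for (j in seq_len(scales)) {
    q <- filt[[j]]$q
    cv <- convolve(xp, rev(q), type = "open")
    lo <- floor(filt[[j]]$center)
    # average the two integer shifts around the half-integer center
    idx <- (pad + 1L):(pad + n)
    w[[j]] <- (cv[idx + lo] + cv[idx + lo + 1L]) / 2
  }
  structure(list(w = w, n = n, scales = scales), class = "ecg_wavelet")
}

#' Signed modulus extrema of a wavelet scale
#'
#' Strict local maxima with positive value and strict local minima with
#' negative value of one coefficient series, restricted to a sample window.
#'
#' @param wt an [ecg_wavelet()] object or a bare numeric coefficient vector.
#' @param scale scale index (ignored when `wt` is a vector).
#' @param from,to 0-based window bounds (inclusive); defaults to the whole
#'   series.
#' @return tibble with 0-based `index`, signed `amplitude`, and `scale`,
#'   sorted by index.  Empty window gives an empty tibble.
#' @export
find_extrema <- function(wt, scale = 1L, from = NULL, to = NULL) {
  w <- if (inherits(wt, "ecg_wavelet")) wt$w[[scale]] else as.numeric(wt)
  n <- length(w)
  if (is.null(from)) from <- 0L
  if (is.null(to)) to <- n - 1L
  from <- max(0L, as.integer(from))
  to <- min(n - 1L, as.integer(to))
  if (from > to) {
    return(tibble(index = integer(), amplitude = numeric(), scale = integer()))
  }
  i <- 2:(n - 1L)
  is_max <- w[i] > w[i - 1L] & w[i] > w[i + 1L] & w[i] > 0
  is_min <- w[i] < w[i - 1L] & w[i] < w[i + 1L] & w[i] < 0
  idx0 <- i[is_max | is_min] - 1L # to 0-based
  idx0 <- idx0[idx0 >= from & idx0 <= to]
  tibble(
    index = as.integer(idx0),
    amplitude = w[idx0 + 1L],
    scale = as.integer(scale)
  )
}

#' Zero crossing between an opposite-sign extremum pair
#'
#' Finds the sample between two opposite-sign modulus extrema where the
#' coefficient series changes sign, with linear sub-sample interpolation
#' rounded to the nearest sample.  When several crossings exist the one
#' nearest the midpoint of the pair is taken.
#'
#' @param wt an [ecg_wavelet()] object or a numeric coefficient vector.
#' @param i_a,i_b 0-based indices of the two extrema (any order).
#' @param scale scale index (ignored when `wt` is a vector).
#' @return 0-based sample index of the crossing.
#' @export
zero_crossing <- function(wt, i_a, i_b, scale = 1L) {
  w <- if (inherits(wt, "ecg_wavelet")) wt$w[[scale]] else as.numeric(wt)
  lo <- min(i_a, i_b)
  hi <- max(i_a, i_b)
  if (lo == hi) abort("Extremum pair must have distinct indices.")
  va <- w[lo + 1L]
  vb <- w[hi + 1L]
  if (sign(va) == sign(vb)) {
    abort("No zero crossing: the two extrema have the same sign.")
  }
  seg <- w[(lo + 1L):(hi + 1L)]
  s <- sign(seg)
  ch <- which(s[-length(s)] * s[-1L] <= 0 & s[-length(s)] != s[-1L])
  if (length(ch) == 0) abort("No sign change between the extremum pair.")
  mid <- (length(seg) + 1) / 2
  k <- ch[which.min(abs(ch + 0.5 - mid))]
  y0 <- seg[k]
  y1 <- seg[k + 1L]
  frac <- if (y0 == y1) 0.5 else y0 / (y0 - y1)
  as.integer(round(lo + (k - 1L) + frac))
}
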