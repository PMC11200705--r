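# IIR filter design and zero-phase filtering.
#
# No DSP package is available in the target stack, so the 4th-order
# Butterworth high-pass and the forward-backward (zero-phase) filter are
# implemented here from first principles: analog Butterworth prototype ->
# lowpass-to-highpass transform -> bilinear transform, and a SciPy-style
# filtfilt with odd-reflection padding and steady-state initial conditions.

# polynomial coefficients (highest power first) from complex roots
.poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

#' Design a digital Butterworth high-pass filter
#'
#' @param order filter order (default 4).
#' @param cutoff_hz cutoff frequency in Hz.
#' @param sample_rate_hz sampling rate in Hz; `cutoff_hz` must be below the
#'   Nyquist frequency.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (length `order + 1`, `a[1] == 1`).
#' @export
butter_highpass <- function(order = 4L, cutoff_hz, sample_rate_hz) {
  stopifnot(order >= 1L, cutoff_hz > 0, sample_rate_hz > 0)
  if (cutoff_hz >= sample_rate_hz / 2)
    stop("cutoff_hz must be below the Nyquist frequency (sample_rate_hz / 2)")
  n <- as.integer(order)
  k <- seq_len(n)
  # analog lowpass prototype poles on the unit circle, left half-plane
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warped analog cutoff, then lowpass -> highpass: p -> wc / p
  wc <- 2 * sample_rate_hz * tan(pi * cutoff_hz / sample_rate_hz)
  p_hp <- wc / p_lp
  z_hp <- rep(0 + 0i, n)
  gain <- Re(prod(-p_lp))           # prod(-zeros) = 1 (no prototype zeros)
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * sample_rate_hz
  gain <- gain * Re(prod(fs2 - z_hp) / prod(fs2 - p_hp))
  z_d <- (fs2 + z_hp) / (fs2 - z_hp)
  p_d <- (fs2 + p_hp) / (fs2 - p_hp)
  b <- Re(gain * .poly_from_roots(z_d))
  a <- Re(.poly_from_roots(p_d))
  list(b = b, a = a)
}

# steady-state initial filter state for a unit step (scipy lfilter_zi)
.lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)           # companion matrix of a
  comp[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp), B)
}

# direct form II transposed IIR filter with initial state zi
.lfilter <- function(b, a, x, zi = NULL) {
  nb <- length(b); nc <- max(nb, length(a)) - 1L
  z <- if (is.null(zi)) numeric(nc) else zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1L] * xm + z[1L]
    if (nc > 1L) {
      for (i in seq_len(nc - 1L))
        z[i] <- b[i + 1L] * xm + z[i + 1L] - a[i + 1L] * ym
    }
    z[nc] <- b[nc + 1L] * xm - a[nc + 1L] * ym
    y[m] <- ym
  }
  y
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter twice, forward and reversed, so the net phase response
#' is zero and event timing is preserved. The signal is extended at both ends
#' by odd reflection before filtering to suppress edge transients.
#'
#' @param b,a filter coefficients as returned by [butter_highpass()].
#' @param x numeric vector to filter.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  ntaps <- max(length(a), length(b))
  padlen <- 3L * ntaps
  if (length(x) <= padlen)
    stop("signal must be longer than 3 * filter order samples")
  pre <- 2 * x[1L] - x[(padlen + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - padlen)]
  ext <- c(pre, x, post)
  zi <- .lfilter_zi(b, a)
  y <- .lfilter(b, a, ext, zi * ext[1L])
  y <- rev(.lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + length(x))]
}

#' Find local maxima with prominence and separation constraints
#'
#' Scale-aware peak picking: candidate local maxima are kept if their
#' topographic prominence reaches `min_prominence`, then peaks closer than
#' `min_distance` samples to a taller accepted peak are discarded.
#'
#' @param x numeric vector.
#' @param min_distance minimum separation between returned peaks, in samples.
#' @param min_prominence minimum prominence (same units as `x`).
#' @return Strictly increasing integer vector of peak indices (1-based).
#' @export
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    j <- i; lmin <- h
    while (j > 1L && x[j - 1L] <= h) { j <- j - 1L; if (x[j] < lmin) lmin <- x[j] }
    j <- i; rmin <- h
    while (j < n && x[j + 1L] <= h) { j <- j + 1L; if (x[j] < rmin) rmin <- x[j] }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  ord <- keep[order(x[keep], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_distance))
      accepted <- c(accepted, i)
  }
  sort(accepted)
}
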