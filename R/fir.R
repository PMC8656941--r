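#' Least-squares linear-phase FIR band-pass design
#'
#' Designs an odd-length, symmetric (type-I linear-phase) FIR band-pass
#' filter as the least-squares fit, over the whole frequency axis, to a
#' band-pass target whose edges are smoothed by a triangular spline of the
#' requested transition width.  Because the target is defined everywhere
#' (no don't-care regions) the optimum is the truncated Fourier series of
#' the target, which has a closed form: no linear system is solved, so very
#' long filters (thousands of taps, as needed for sub-hertz transitions) are
#' cheap to design.
#'
#' @param order Filter order (number of taps minus one); coerced to even so
#'   the filter has an integer group delay.
#' @param f_lo,f_hi Pass-band edges in Hz (`f_lo = 0` gives a low-pass).
#' @param fs Sampling frequency in Hz.
#' @param tw Transition width in Hz on each side of the pass band (default
#'   1 Hz); automatically narrowed where a band edge sits closer than `tw`
#'   to 0 or to the Nyquist frequency.
#' @return Numeric vector of `order + 1` filter coefficients, symmetric
#'   about its midpoint.
#' @export
fir_ls <- function(order, f_lo, f_hi, fs, tw = 1) {
  stopifnot(order >= 2, f_hi > f_lo, f_hi < fs / 2, f_lo >= 0, tw > 0)
  m <- floor(order / 2)
  n <- seq(-m, m)

  # least-squares-optimal low-pass for a brick-wall target convolved with a
  # unit-area triangle of half-width `a` (radians/sample): coefficients are
  # the ideal-low-pass series multiplied by sinc^2(a n / 2)
  lp <- function(fc, a) {
    w <- 2 * pi * fc / fs
    h <- ifelse(n == 0, w / pi, sin(w * n) / (pi * n))
    if (a > 0) {
      s <- ifelse(n == 0, 1, (sin(a * n / 2) / (a * n / 2))^2)
      h <- h * s
    }
    h
  }

  tw_hi <- min(tw, fs / 2 - f_hi) # keep the whole transition inside (0, Nyquist)
  h <- lp(f_hi + tw_hi / 2, pi * tw_hi / fs)
  if (f_lo > 0) {
    tw_lo <- min(tw, f_lo)
    h <- h - lp(f_lo - tw_lo / 2, pi * tw_lo / fs)
  }
  h
}

# default band-pass order: long enough both for the 3-cycles-at-f_lo rule of
# thumb and for the 1 Hz transition contract, capped at one third of the
# signal length so two-pass edge transients never swallow the whole epoch
fir_default_order <- function(f_lo, fs, len, tw = 1) {
  ord <- max(round(3 * fs / max(f_lo, 0.1)), round(4 * fs / tw))
  ord <- min(ord, floor(len / 3))
  if (ord < 8) abort("signal too short for a usable band-pass filter")
  ord
}

#' Zero-phase FIR band-pass filtering
#'
#' Band-pass filters each row of a multichannel time-series with a
#' least-squares linear-phase FIR filter applied in both directions
#' (forward and time-reversed), giving exactly zero phase distortion.  The
#' two passes are computed as a single FFT-domain convolution with the
#' filter's autocorrelation, which is algebraically identical to
#' forward-backward filtering with zero-padded ends.
#'
#' @param x Numeric matrix (regions x samples) or vector.
#' @param f_lo,f_hi Pass-band edges in Hz.
#' @param fs Sampling frequency in Hz.
#' @param order FIR order; default chosen from `f_lo`, `fs` and the signal
#'   length (see [fir_ls()]), capped at one third of the signal length.
#' @param tw Transition width in Hz (default 1).
#' @return Filtered data with the same shape as `x`.  The attribute
#'   `"fir_order"` records the order actually used (relevant for discarding
#'   edge transients downstream).
#' @export
bandpass_fir <- function(x, f_lo, f_hi, fs, order = NULL, tw = 1) {
  vec_in <- is.null(dim(x))
  x <- as_matrix_ts(x)
  nT <- ncol(x)
  order <- order %||% fir_default_order(f_lo, fs, nT, tw)
  if (order > nT) abort("FIR order infeasible for this signal length")
  h <- fir_ls(order, f_lo, f_hi, fs, tw)
  L <- length(h)

  # two-pass kernel: conv(h, rev(h)) = conv(h, h) for symmetric h
  nf <- stats::nextn(nT + 2L * L, 2)
  H <- fft(c(h, numeric(nf - L)))
  X <- stats::mvfft(rbind(t(x), matrix(0, nf - nT, nrow(x))))
  Y <- Re(stats::mvfft(X * (H * H), inverse = TRUE)) / nf
  out <- t(Y[L:(L + nT - 1L), , drop = FALSE])

  attr(out, "fir_order") <- order
  if (vec_in) {
    out <- drop(out)
    attr(out, "fir_order") <- order
  }
  out
}

#' Analytic signal and amplitude envelope
#'
#' Computes the analytic signal of each row via the frequency-domain
#' construction (positive frequencies doubled, negative zeroed), and the
#' amplitude envelope as its magnitude.
#'
#' @param x Numeric matrix (regions x samples) or vector.
#' @return `analytic_signal()`: complex matrix/vector of the same shape;
#'   `amplitude_envelope()`: its modulus.
#' @export
analytic_signal <- function(x) {
  vec_in <- is.null(dim(x))
  x <- as_matrix_ts(x)
  nT <- ncol(x)
  w <- numeric(nT)
  if (nT %% 2 == 0) {
    w[c(1L, nT / 2 + 1L)] <- 1
    w[2:(nT / 2)] <- 2
  } else {
    w[1L] <- 1
    w[2:((nT + 1L) / 2)] <- 2
  }
  A <- stats::mvfft(stats::mvfft(t(x)) * w, inverse = TRUE) / nT
  out <- t(A)
  if (vec_in) drop(out) else out
}

#' @rdname analytic_signal
#' @export
amplitude_envelope <- function(x) Mod(analytic_signal(x))
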