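#' Butterworth band-pass design in second-order sections
#'
#' Designs a Butterworth IIR band-pass filter in zero-pole-gain form and packs
#' it into second-order sections (biquad cascade) for numerically stable
#' application. `order` is the order of the final band-pass filter, so an
#' order-10 band-pass comes from an order-5 low-pass prototype.
#'
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Final band-pass filter order (even). Default 10.
#' @return A matrix with one row per section and columns
#'   `b0, b1, b2, a1, a2` (`a0` normalized to 1).
#' @keywords internal
butter_bandpass_sos <- function(low, high, fs, order = 10) {
  if (order %% 2 != 0 || order < 2) stop("`order` must be a positive even integer.", call. = FALSE)
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop(sprintf(
      "invalid band edges: need 0 < low < high < fs/2 (got %g-%g Hz at fs %g).",
      low, high, fs
    ), call. = FALSE)
  }
  n <- order / 2
  # analog Butterworth low-pass prototype (unit cutoff): poles on the left
  # half unit circle, no finite zeros, gain 1
  k <- seq_len(n)
  sp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # bilinear pre-warp, then band transform in s and bilinear to z
  t_samp <- 2
  w <- (2 / t_samp) * tan(pi * c(low, high) / fs)
  st <- signal::sftrans(Sz = numeric(0), Sp = sp, Sg = 1, W = w, stop = FALSE)
  zz <- signal::bilinear(Sz = st$zero, Sp = st$pole, Sg = st$gain, T = t_samp)
  zpk_to_sos(zz$zero, zz$pole, Re(zz$gain))
}

# Pair conjugate poles/zeros into biquads. Butterworth band-pass digital zeros
# sit at z = +1 and z = -1; each section receives one of each so every biquad
# is itself a band-pass. Gain is spread evenly across sections.
zpk_to_sos <- function(zeros, poles, gain) {
  n_sec <- ceiling(length(poles) / 2)
  # keep conjugate pairs together: pair each upper-half pole with its
  # conjugate, pair real poles among themselves, narrowest sections first
  tol <- 1e-10
  upper <- poles[Im(poles) > tol]
  realp <- sort(Re(poles[abs(Im(poles)) <= tol]), decreasing = TRUE)
  pairs <- c(
    lapply(upper[order(-Mod(upper))], function(p) c(p, Conj(p))),
    if (length(realp) > 0) {
      split(realp, ceiling(seq_along(realp) / 2))
    }
  )
  stopifnot(length(pairs) == n_sec)
  pos <- zeros[Re(zeros) >= 0]
  neg <- zeros[Re(zeros) < 0]
  g1 <- abs(gain)^(1 / n_sec)
  sos <- matrix(0, n_sec, 5, dimnames = list(NULL, c("b0", "b1", "b2", "a1", "a2")))
  for (s in seq_len(n_sec)) {
    p <- pairs[[s]]
    a <- Re(poly_from_roots(p))
    z <- c(
      if (length(pos) >= s) pos[s],
      if (length(neg) >= s) neg[s]
    )
    b <- Re(poly_from_roots(z)) * g1 * (if (s == 1) sign(gain) else 1)
    a <- c(a, rep(0, 3 - length(a)))
    b <- c(b, rep(0, 3 - length(b)))
    sos[s, ] <- c(b, a[2:3])
  }
  sos
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Complex frequency response of an SOS cascade at frequencies f (Hz)
sos_freq_response <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(z))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, "b0"] + sos[s, "b1"] * z + sos[s, "b2"] * z^2
    den <- 1 + sos[s, "a1"] * z + sos[s, "a2"] * z^2
    h <- h * num / den
  }
  h
}

# One biquad, vectorized: MA part then AR recursion (both in C via
# stats::filter), initialized at step steady state w.r.t. the first sample so
# that odd-reflection padding suffices for zero-phase application.
biquad_filter <- function(b, a, x) {
  n <- length(x)
  if (n == 0) return(x)
  x0 <- x[1]
  den <- 1 + a[1] + a[2]
  y_ss <- if (abs(den) > .Machine$double.eps) x0 * sum(b) / den else 0
  xe <- c(x0, x0, x)
  v <- stats::filter(xe, b, method = "convolution", sides = 1)[3:(n + 2)]
  y <- stats::filter(v, -a, method = "recursive", init = c(y_ss, y_ss))
  as.numeric(y)
}

sosfilt <- function(sos, x) {
  for (s in seq_len(nrow(sos))) {
    x <- biquad_filter(sos[s, 1:3], sos[s, 4:5], x)
  }
  x
}

# forward-backward SOS filtering with odd-reflection edge padding
sosfiltfilt <- function(sos, x, padlen) {
  n <- length(x)
  if (n <= padlen) {
    stop(sprintf(
      "signal too short for zero-phase filtering: %d samples, need > %d for the edge padding.",
      n, padlen
    ), call. = FALSE)
  }
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  y <- sosfilt(sos, ext)
  y <- rev(sosfilt(sos, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters an EEG signal with a Butterworth IIR filter realized as a
#' cascade of second-order sections and applied forward-backward (zero phase).
#' The default order-10 design with a 0.3-30 Hz band is the standard broad-band
#' conditioning applied to sleep EEG before spindle scoring; the same routine
#' with an 11-16 Hz band isolates the sigma band.
#'
#' Forward-backward application squares the magnitude response and cancels the
#' phase, so a long in-band sinusoid passes with zero lag. Edges are handled by
#' odd-reflection padding of `padlen` samples (default three times the filter
#' order).
#'
#' @param signal An [eeg_signal()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Band-pass filter order (even), default 10.
#' @param padlen Edge padding length in samples for the forward-backward pass;
#'   default `3 * order`.
#' @return A filtered [eeg_signal()] of identical length, rate and start time.
#' @examples
#' t <- seq(0, 10, by = 1 / 100)
#' s <- eeg_signal(sin(2 * pi * 13 * t), fs = 100)
#' f <- bandpass_filter(s, 0.3, 30)
#' sd(f$samples) / sd(s$samples) # ~1: 13 Hz is in the passband
#' @export
bandpass_filter <- function(signal, low, high, order = 10, padlen = 3 * order) {
  stopifnot(inherits(signal, "eeg_signal"))
  sos <- butter_bandpass_sos(low, high, signal$fs, order = order)
  y <- sosfiltfilt(sos, signal$samples, padlen = padlen)
  eeg_signal(y, fs = signal$fs, start_time = signal$start_time)
}

#' Polyphase resampling to a target rate
#'
#' Resamples a signal by a rational factor `p/q` with an FIR anti-aliasing
#' low-pass (zero-stuff by `p`, filter, take every `q`-th sample), the
#' polyphase scheme used to bring sleep EEG to a common 100 Hz processing
#' rate. The FIR cutoff sits at the lower of the two Nyquist frequencies and
#' the group delay is compensated, so the output is aligned with the input and
#' `length(out) == round(n * target_fs / fs)`.
#'
#' @param signal An [eeg_signal()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @param taps_per_phase FIR length per polyphase branch; the filter has
#'   `2 * taps_per_phase * max(p, q) + 1` taps. Default 10.
#' @return An [eeg_signal()] at `target_fs`.
#' @examples
#' x <- eeg_signal(sin(2 * pi * 13 * (0:2559) / 256), fs = 256)
#' y <- resample_to(x, 100)
#' length(y$samples) # 1000
#' @export
resample_to <- function(signal, target_fs, taps_per_phase = 10) {
  stopifnot(inherits(signal, "eeg_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1 || is.na(target_fs) || target_fs <= 0) {
    stop("`target_fs` must be a single positive number (Hz).", call. = FALSE)
  }
  if (target_fs == signal$fs) return(signal)
  pq <- rational_ratio(target_fs / signal$fs)
  p <- pq[1]; q <- pq[2]
  x <- signal$samples
  n <- length(x)
  n_out <- round(n * target_fs / signal$fs)
  n_taps <- 2 * taps_per_phase * max(p, q) + 1
  h <- signal::fir1(n_taps - 1, 1 / max(p, q), type = "low")
  # normalize each polyphase branch to unit DC gain so constants are exact
  phase <- (seq_along(h) - 1) %% p
  for (r in 0:(p - 1)) {
    idx <- phase == r
    h[idx] <- h[idx] / sum(h[idx])
  }
  delay <- (n_taps - 1) / 2
  xu <- numeric(n * p + delay + n_out * q) # tail padding covers the last outputs
  xu[seq(1, by = p, length.out = n)] <- x
  yf <- stats::filter(xu, h, method = "convolution", sides = 1)
  idx <- (seq_len(n_out) - 1) * q + delay + 1
  y <- as.numeric(yf[idx])
  y[is.na(y)] <- 0
  eeg_signal(y, fs = target_fs, start_time = signal$start_time)
}

# best small-integer rational approximation by continued fractions
rational_ratio <- function(x, tol = 1e-9, max_den = 1e6) {
  a0 <- floor(x)
  p0 <- 1; q0 <- 0; p1 <- a0; q1 <- 1
  frac <- x - a0
  while (abs(p1 / q1 - x) > tol * x && q1 < max_den) {
    a <- floor(1 / frac)
    frac <- 1 / frac - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(as.integer(p1), as.integer(q1))
}
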