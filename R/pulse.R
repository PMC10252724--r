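#' Transmit pulse specification
#'
#' Describes the transmitted tone burst in terms of its centre frequency,
#' its length in transducer half cycles, the shape of its complex baseband
#' envelope, and the fast-time sampling rate of the received IQ data.
#' The pulse duration is `half_cycles / (2 * fc)` seconds; shorter pulses
#' carry a wider band of transmitted frequencies, which is what the
#' multifrequency estimator averages over.
#'
#' @param fc Centre transmit frequency in Hz.
#' @param half_cycles Pulse length in transducer half cycles (integer >= 1).
#' @param envelope Envelope shape: `"rectangular"`, `"bartlett"` or
#'   `"gaussian"`.
#' @param fs_fast Fast-time sampling rate in Hz; must be at least `4 * fc`
#'   so the pulse spectrum is resolvable in the sampled band.
#' @return An object of class `pulse_spec`.
#' @examples
#' pulse_spec(fc = 5e6, half_cycles = 4)
#' @export
pulse_spec <- function(fc, half_cycles, envelope = c("rectangular", "bartlett", "gaussian"),
                       fs_fast = 4 * fc) {
  stopifnot_scalar(fc, "fc", positive = TRUE)
  stopifnot_scalar(fs_fast, "fs_fast", positive = TRUE)
  if (!is.numeric(half_cycles) || length(half_cycles) != 1L ||
      half_cycles < 1 || half_cycles != round(half_cycles)) {
    stop("'half_cycles' must be an integer >= 1")
  }
  if (fs_fast < 4 * fc) stop("'fs_fast' must be at least 4 * fc")
  envelope <- match.arg(envelope)
  structure(
    list(fc = fc, half_cycles = as.integer(half_cycles), envelope = envelope,
         fs_fast = fs_fast, duration = half_cycles / (2 * fc)),
    class = "pulse_spec"
  )
}

# Continuous-time complex baseband envelope a(t), unit peak, support [0, T].
envelope_fun <- function(pulse) {
  T <- pulse$duration
  # rectangular support is half-open [0, T) so a T-second burst occupies
  # exactly T * fs samples and its discrete spectrum keeps the 0.886/T
  # mainlobe width of the continuous sinc^2
  switch(pulse$envelope,
    rectangular = function(t) as.numeric(t >= 0 & t < T) + 0i,
    bartlett = function(t) {
      inside <- t >= 0 & t <= T
      (pmax(0, 1 - abs(2 * t / T - 1)) * inside) + 0i
    },
    gaussian = function(t) {
      s <- T / 6
      inside <- t >= 0 & t <= T
      (exp(-(t - T / 2)^2 / (2 * s^2)) * inside) + 0i
    }
  )
}

#' Sample the complex baseband envelope of a transmit pulse
#'
#' Returns the unit-peak complex envelope of the tone burst described by a
#' [pulse_spec()], sampled at the fast-time rate over its full duration
#' `half_cycles / (2 * fc)`.
#'
#' @param pulse A [pulse_spec()].
#' @return A list with elements `a` (complex samples), `t` (sample times in
#'   seconds), `fs_fast` and `duration`.
#' @examples
#' p <- make_pulse(pulse_spec(5e6, 4))
#' p$duration # 4e-07 s
#' @export
make_pulse <- function(pulse) {
  if (!inherits(pulse, "pulse_spec")) stop("'pulse' must be a pulse_spec")
  T <- pulse$duration
  n <- floor(T * pulse$fs_fast) + 1L
  t <- (0:(n - 1L)) / pulse$fs_fast
  a <- envelope_fun(pulse)(t)
  list(a = a, t = t, fs_fast = pulse$fs_fast, duration = T)
}

#' Power spectral density of a pulse envelope
#'
#' Computes the zero-padded power spectrum |U(f)|^2 of a complex baseband
#' envelope, on a frequency axis of offsets from the carrier. The padding is
#' chosen so the bin spacing does not exceed `df_max` (10 kHz by default),
#' giving sub-percent resolution of megahertz-scale bandwidths. This is the
#' weighting term used by the multifrequency spectral average, and the
#' spectrum whose full width at half maximum defines the transmitted
#' bandwidth.
#'
#' @param envelope Either the list returned by [make_pulse()] or a numeric /
#'   complex vector of envelope samples.
#' @param fs_fast Sampling rate in Hz (taken from `envelope` when it is a
#'   [make_pulse()] result).
#' @param df_max Maximum bin spacing in Hz.
#' @return A list with `freq` (Hz, offsets from the carrier, strictly
#'   increasing) and `power` (non-negative).
#' @export
pulse_power_spectrum <- function(envelope, fs_fast = NULL, df_max = 1e4) {
  if (is.list(envelope)) {
    if (is.null(fs_fast)) fs_fast <- envelope$fs_fast
    envelope <- envelope$a
  }
  if (length(envelope) == 0L) stop("empty envelope")
  if (is.null(fs_fast)) stop("'fs_fast' required when passing raw samples")
  stopifnot_scalar(df_max, "df_max", positive = TRUE)
  nfft <- max(length(envelope), ceiling(fs_fast / df_max))
  nfft <- 2^ceiling(log2(nfft))
  x <- c(as.complex(envelope), complex(nfft - length(envelope)))
  p <- Mod(stats::fft(x))^2
  ord <- dft_shift_order(nfft)
  list(freq = dft_freqs(nfft, fs_fast)[ord], power = p[ord])
}

#' Full width at half maximum of a single-peaked power spectrum
#'
#' Measures the transmitted bandwidth as the full width at half the peak
#' power, with sub-bin linear interpolation at the two half-power crossings.
#' When several bins tie for the global maximum, the contiguous half-power
#' span of the widest tied peak is used, ties broken toward the lower
#' frequency.
#'
#' @param spectrum A list with `freq` and `power` as returned by
#'   [pulse_power_spectrum()].
#' @return Bandwidth in Hz.
#' @export
measure_fwhm_bandwidth <- function(spectrum) {
  f <- spectrum$freq
  p <- spectrum$power
  if (length(p) < 3L || length(f) != length(p)) stop("malformed spectrum")
  pk <- max(p)
  if (!is.finite(pk) || pk <= 0) stop("no peak: spectrum is flat or all zero")
  half <- pk / 2
  if (min(p) >= half) stop("no peak: spectrum never falls below half power")
  peaks <- which(p == pk)
  spans <- lapply(peaks, function(i) half_power_span(f, p, i, half))
  widths <- vapply(spans, function(s) s[2L] - s[1L], numeric(1))
  best <- which(widths == max(widths))[1L] # tie -> lower frequency
  widths[best]
}

# Contiguous half-power span containing peak index i, with linear
# interpolation at the crossings; clamped at the axis ends.
half_power_span <- function(f, p, i, half) {
  n <- length(p)
  j <- i
  while (j > 1L && p[j - 1L] >= half) j <- j - 1L
  left <- if (j == 1L) f[1L] else {
    f[j - 1L] + (half - p[j - 1L]) / (p[j] - p[j - 1L]) * (f[j] - f[j - 1L])
  }
  k <- i
  while (k < n && p[k + 1L] >= half) k <- k + 1L
  right <- if (k == n) f[n] else {
    f[k] + (half - p[k]) / (p[k + 1L] - p[k]) * (f[k + 1L] - f[k])
  }
  c(left, right)
}
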