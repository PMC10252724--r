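#' Slow-time windowing specification
#'
#' Length and overlap of the sliding slow-time analysis window used for
#' Welch-style segment averaging and for sonogram frames. The window family
#' is triangular (Bartlett).
#'
#' @param win_slow Window length in pulse lines (>= 2).
#' @param overlap_frac Fractional overlap between consecutive windows,
#'   `0 <= overlap_frac < 1`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(win_slow = 128, overlap_frac = 0.75) {
  if (!is.numeric(win_slow) || win_slow < 2 || win_slow != round(win_slow)) {
    stop("'win_slow' must be an integer >= 2")
  }
  stopifnot_scalar(overlap_frac, "overlap_frac")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("'overlap_frac' must lie in [0, 1)")
  structure(list(win_slow = as.integer(win_slow), overlap_frac = overlap_frac),
            class = "window_spec")
}

window_hop <- function(win) max(1L, as.integer(round(win$win_slow * (1 - win$overlap_frac))))

segment_starts <- function(n_slow, win) {
  hop <- window_hop(win)
  if (win$win_slow > n_slow) stop("'win_slow' exceeds the number of pulse lines")
  seq(1L, n_slow - win$win_slow + 1L, by = hop)
}

#' Segment an IQ dataset into windowed pulse-line blocks
#'
#' Cuts the region of interest (a fast-time row range) into consecutive
#' slow-time segments of `win_slow` pulse lines with hop
#' `win_slow * (1 - overlap_frac)` (rounded, at least 1).
#'
#' @param iq An [simulate_gate()] `iq_dataset` (or a complex matrix).
#' @param roi Integer vector of fast-time rows to keep; `NULL` for all.
#' @param win A [window_spec()].
#' @return A list of complex sub-matrices with attributes `starts` (first
#'   slow-time index of each segment) and `hop`.
#' @export
segment_pulse_lines <- function(iq, roi = NULL, win = window_spec()) {
  x <- if (inherits(iq, "iq_dataset")) iq$data else iq
  if (!is.matrix(x)) stop("'iq' must be an iq_dataset or a matrix")
  if (is.null(roi)) roi <- seq_len(nrow(x))
  if (length(roi) == 0L) stop("empty region of interest")
  if (any(roi < 1L) || any(roi > nrow(x))) stop("roi outside the fast-time range")
  starts <- segment_starts(ncol(x), win)
  segs <- lapply(starts, function(s) x[roi, s:(s + win$win_slow - 1L), drop = FALSE])
  structure(segs, starts = starts, hop = window_hop(win))
}

#' Apply a Bartlett window to a segment
#'
#' Element-wise multiplication by triangular windows along the chosen axes.
#' Slow-time windowing tapers the truncated pulse-line series before the
#' Fourier transform; fast-time windowing can additionally taper the gate.
#'
#' @param segment Complex matrix (fast-time rows, slow-time columns) or a
#'   vector.
#' @param axes `"slow"`, `"fast"` or `"both"`.
#' @return The windowed segment.
#' @export
apply_bartlett <- function(segment, axes = c("both", "slow", "fast")) {
  axes <- match.arg(axes)
  if (is.null(dim(segment))) {
    return(segment * bartlett_window(length(segment)))
  }
  if (length(segment) == 0L) stop("empty segment")
  if (axes %in% c("fast", "both")) {
    segment <- segment * bartlett_window(nrow(segment))
  }
  if (axes %in% c("slow", "both")) {
    segment <- t(t(segment) * bartlett_window(ncol(segment)))
  }
  segment
}

#' Two-dimensional power spectrum of a windowed segment
#'
#' Squared magnitude of the 2-D DFT of a fast-time-by-slow-time block,
#' normalised so total spectral power equals the windowed-signal energy
#' (Parseval). The fast-time axis is shifted to absolute radiofrequencies
#' about the carrier `fc`; the slow-time axis to Doppler frequencies in
#' `(-prf/2, +prf/2]`.
#'
#' @param segment Complex matrix with at least 2 rows and 2 columns.
#' @param fs_fast Fast-time sampling rate (Hz).
#' @param prf Pulse repetition frequency (Hz).
#' @param fc Centre transmit frequency (Hz).
#' @return An object of class `spectrum2d`: list with `power`
#'   (RF bins x Doppler bins), `f_rf`, `f_d`, `fc`, `prf`, `fs_fast`.
#' @export
fft2d <- function(segment, fs_fast, prf, fc) {
  if (!is.matrix(segment) || nrow(segment) < 2L || ncol(segment) < 2L) {
    stop("degenerate segment: need at least 2 fast-time and 2 slow-time samples")
  }
  n_f <- nrow(segment)
  n_s <- ncol(segment)
  Z <- stats::fft(segment)
  power <- Mod(Z)^2 / (n_f * n_s)
  of <- dft_shift_order(n_f)
  od <- dft_shift_order(n_s)
  structure(
    list(power = power[of, od, drop = FALSE],
         f_rf = fc + dft_freqs(n_f, fs_fast)[of],
         f_d = dft_freqs(n_s, prf)[od],
         fc = fc, prf = prf, fs_fast = fs_fast, lp_cutoff = NULL),
    class = "spectrum2d"
  )
}

#' Doppler-axis low-pass filter
#'
#' Suppresses spectral content approaching the pulse repetition frequency:
#' Doppler components beyond `cutoff_frac * prf/2` are zeroed, with a
#' raised-cosine taper over the top 10% of the passband; the passband
#' interior is untouched.
#'
#' @param spec A [fft2d()] `spectrum2d`.
#' @param cutoff_frac Passband edge as a fraction of the Nyquist Doppler
#'   frequency, `0 < cutoff_frac <= 1`.
#' @return The filtered `spectrum2d`, with the cutoff recorded in
#'   `lp_cutoff`.
#' @export
lowpass_prf <- function(spec, cutoff_frac = 0.9) {
  stopifnot_scalar(cutoff_frac, "cutoff_frac", positive = TRUE)
  if (cutoff_frac > 1) stop("'cutoff_frac' must not exceed 1")
  edge <- cutoff_frac * spec$prf / 2
  gain <- lowpass_gain(spec$f_d, edge)
  spec$power <- t(t(spec$power) * gain)
  spec$lp_cutoff <- edge
  spec
}

# Raised-cosine power gain: unity below 0.9*edge, zero at and beyond edge.
lowpass_gain <- function(f_d, edge) {
  af <- abs(f_d)
  t0 <- 0.9 * edge
  g <- numeric(length(af))
  g[af <= t0] <- 1
  ramp <- af > t0 & af < edge
  g[ramp] <- 0.5 * (1 + cos(pi * (af[ramp] - t0) / (edge - t0)))
  g
}

#' Convert a Doppler shift to an axial velocity
#'
#' Standard Doppler equation `v = c * f_d / (2 * fc * cos(theta))`;
#' positive velocities point toward the transducer.
#'
#' @param f_d Doppler frequency (Hz), referenced to the carrier.
#' @param fc Centre transmit frequency (Hz).
#' @param c Speed of sound (m/s).
#' @param theta Beam-to-flow angle (radians), must have `cos(theta) > 0`.
#' @return Velocity in m/s.
#' @examples
#' doppler_to_velocity(1298.7, fc = 5e6) # ~0.2 m/s
#' @export
doppler_to_velocity <- function(f_d, fc, c = 1540, theta = 0) {
  if (cos(theta) <= 1e-9) stop("'theta' must have positive cosine")
  c * f_d / (2 * fc * cos(theta))
}

#' Velocity spectrum container
#'
#' Power versus Doppler frequency / velocity, the common output container of
#' [mfudsa_spectrum()] and [baseline_1d_spectrum()]. Mostly used internally,
#' but exported so spectra from external sources can be fed to the metrics
#' functions.
#'
#' @param power Non-negative power values.
#' @param f_d Doppler frequencies (Hz, referenced to the carrier),
#'   strictly increasing.
#' @param fc Carrier frequency (Hz).
#' @param prf Pulse repetition frequency (Hz).
#' @param c Speed of sound (m/s).
#' @param theta Beam-to-flow angle (radians).
#' @param bw Integration bandwidth (Hz), if any.
#' @param win_slow Slow-time window length used, if any.
#' @param lp_cutoff Doppler low-pass edge (Hz), if any.
#' @param method Estimator label.
#' @param n_segments Number of averaged segments.
#' @return An object of class `velocity_spectrum` with fields `power`,
#'   `f_d`, `v` and `meta`.
#' @export
velocity_spectrum <- function(power, f_d, fc, prf, c = 1540, theta = 0,
                              bw = NA_real_, win_slow = NA_integer_,
                              lp_cutoff = NULL, method = "mfudsa",
                              n_segments = 1L) {
  structure(
    list(power = power, f_d = f_d,
         v = doppler_to_velocity(f_d, fc, c, theta),
         meta = list(fc = fc, prf = prf, c = c, theta = theta, bw = bw,
                     win_slow = win_slow, lp_cutoff = lp_cutoff,
                     method = method, n_segments = n_segments)),
    class = "velocity_spectrum"
  )
}

#' Multifrequency spectral scaling and averaging
#'
#' Collapses a two-dimensional (RF x Doppler) power spectrum onto a single
#' Doppler axis referenced to the carrier. Every RF column within the
#' transmitted band `[fc - BW/2, fc + BW/2]` is read at the scaled Doppler
#' frequency `f_d * f_RF / fc` (linear interpolation, zero outside its
#' support), the columns are integrated over `f_RF` by the trapezoidal
#' rule, and the result is normalised by the trapezoidal integral of the
#' pulse power spectrum `|U(f_RF - fc)|^2` over the same limits. Because a
#' moving scatterer's Doppler shift is proportional to `f_RF`, the scaling
#' aligns the per-column spectral peaks so they average coherently instead
#' of smearing.
#'
#' @param spec A `spectrum2d`, usually after [lowpass_prf()].
#' @param bw Integration bandwidth in Hz (the transmitted bandwidth, e.g.
#'   from [measure_fwhm_bandwidth()]).
#' @param upsd Pulse power spectrum (list with `freq`, `power`) used as the
#'   normalising weight; `NULL` for a flat unit weight.
#' @param fc Carrier frequency; defaults to the one recorded on `spec`.
#' @param c,theta Sound speed and beam angle used for the velocity axis.
#' @return A `velocity_spectrum` on the slow-time DFT bin grid of `spec`.
#' @export
spectral_scale_average <- function(spec, bw, upsd = NULL, fc = spec$fc,
                                   c = 1540, theta = 0) {
  stopifnot_scalar(bw, "bw", positive = TRUE)
  lo <- fc - bw / 2
  hi <- fc + bw / 2
  if (lo < min(spec$f_rf) || hi > max(spec$f_rf)) {
    stop("integration bandwidth exceeds the RF axis span")
  }
  rows <- which(spec$f_rf >= lo & spec$f_rf <= hi)
  if (length(rows) < 2L) {
    stop("integration bandwidth narrower than the RF bin spacing")
  }
  f_rf <- spec$f_rf[rows]
  w <- trapz_weights(f_rf)
  u <- if (is.null(upsd)) {
    rep(1, length(rows))
  } else {
    du <- upsd$freq[2L] - upsd$freq[1L]
    interp_uniform(upsd$power, upsd$freq[1L], du, f_rf - fc)
  }
  norm <- sum(w * u)
  if (!is.finite(norm) || norm <= 0) stop("non-positive spectral normaliser")

  f_d <- spec$f_d
  dfd <- f_d[2L] - f_d[1L]
  num <- numeric(length(f_d))
  for (i in seq_along(rows)) {
    s_i <- f_rf[i] / fc
    num <- num + w[i] *
      interp_uniform(spec$power[rows[i], ], f_d[1L], dfd, f_d * s_i)
  }
  velocity_spectrum(num / norm, f_d, fc = fc, prf = spec$prf, c = c,
                    theta = theta, bw = bw, lp_cutoff = spec$lp_cutoff)
}
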