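# End-to-end spectral estimators: the 2-D multifrequency pipeline, the
# matched 1-D baseline, and sonogram assembly.

# Zero-pad the slow-time axis of a windowed segment (or vector) so the
# Doppler grid oversamples the window mainlobe; removes the scalloping and
# interpolation bias of the spectral-scaling quadrature.
pad_slow <- function(seg, pad_factor) {
  if (pad_factor <= 1) return(seg)
  if (is.matrix(seg)) {
    cbind(seg, matrix(0 + 0i, nrow(seg), (pad_factor - 1L) * ncol(seg)))
  } else {
    c(seg, complex((pad_factor - 1L) * length(seg)))
  }
}

# Per-segment 2-D stage shared by mfudsa_spectrum() and build_sonogram().
mfudsa_segment <- function(seg, iq, bw, upsd, cutoff_frac, window_axes,
                           pad_factor = 4L) {
  seg <- apply_bartlett(seg, axes = window_axes)
  seg <- pad_slow(seg, pad_factor)
  sp <- fft2d(seg, fs_fast = iq$pulse$fs_fast, prf = iq$acq$prf, fc = iq$pulse$fc)
  sp <- lowpass_prf(sp, cutoff_frac)
  spectral_scale_average(sp, bw = bw, upsd = upsd, fc = iq$pulse$fc,
                         c = iq$acq$c, theta = iq$acq$theta)
}

#' Multifrequency 2-D Doppler velocity spectrum
#'
#' Runs the full two-dimensional estimation chain on an IQ dataset:
#' slow-time segmentation, Bartlett windowing, 2-D DFT, Doppler-axis
#' low-pass, multifrequency spectral scaling/averaging over the transmitted
#' bandwidth, and Welch-style averaging of the per-segment spectra. The
#' integration bandwidth defaults to the measured full width at half
#' maximum of the dataset's own pulse spectrum.
#'
#' By default only the slow-time axis is Bartlett windowed: the echo
#' envelope is compactly supported inside the gate, so fast-time truncation
#' contributes no sidelobes, whereas a fast-time taper would widen each RF
#' column's response and correlate neighbouring RF bins, weakening the
#' multifrequency averaging. Set `window_axes = "both"` to taper both axes.
#'
#' @param iq An `iq_dataset`.
#' @param roi Fast-time rows to analyse (`NULL` for all).
#' @param win A [window_spec()].
#' @param cutoff_frac Doppler low-pass edge (fraction of `prf/2`).
#' @param window_axes Axes to Bartlett window: `"slow"`, `"fast"`, `"both"`.
#' @param bw Integration bandwidth in Hz; `NULL` to measure it from the
#'   pulse.
#' @param pad_factor Slow-time zero-padding factor; the Doppler grid has
#'   `pad_factor * win_slow` bins, oversampling the window mainlobe so the
#'   scaling interpolation is unbiased. Resolution is still set by
#'   `win_slow`.
#' @return A `velocity_spectrum`.
#' @examples
#' iq <- simulate_gate(velocity_waveform("constant", v_const = 0.2),
#'                     pulse_spec(5e6, 4),
#'                     acquisition_spec(prf = 4000, n_slow = 512, seed = 1))
#' vs <- mfudsa_spectrum(iq)
#' vs$v[which.max(vs$power)] # ~0.2 m/s
#' @export
mfudsa_spectrum <- function(iq, roi = NULL, win = window_spec(),
                            cutoff_frac = 0.9, window_axes = "slow",
                            bw = NULL, pad_factor = 4L) {
  if (!inherits(iq, "iq_dataset")) stop("'iq' must be an iq_dataset")
  upsd <- pulse_power_spectrum(make_pulse(iq$pulse))
  if (is.null(bw)) bw <- measure_fwhm_bandwidth(upsd)
  segs <- segment_pulse_lines(iq, roi = roi, win = win)
  acc <- NULL
  for (seg in segs) {
    vs <- mfudsa_segment(seg, iq, bw, upsd, cutoff_frac, window_axes, pad_factor)
    acc <- if (is.null(acc)) vs$power else acc + vs$power
  }
  out <- vs
  out$power <- acc / length(segs)
  out$meta$win_slow <- win$win_slow
  out$meta$n_segments <- length(segs)
  out$meta$method <- "mfudsa"
  out
}

#' Conventional 1-D spectral-Doppler baseline
#'
#' The matched one-dimensional architecture: fast-time samples within the
#' region of interest are summed coherently (range-gate integration), the
#' resulting slow-time series is cut into Bartlett-windowed segments, and
#' the per-segment power spectra are averaged. The velocity axis is
#' referenced to the carrier only, so all transmitted frequency components
#' are attributed to `fc`.
#'
#' @inheritParams mfudsa_spectrum
#' @return A `velocity_spectrum`.
#' @export
baseline_1d_spectrum <- function(iq, roi = NULL, win = window_spec(),
                                 pad_factor = 4L) {
  if (!inherits(iq, "iq_dataset")) stop("'iq' must be an iq_dataset")
  x <- iq$data
  if (is.null(roi)) roi <- seq_len(nrow(x))
  if (length(roi) == 0L) stop("empty region of interest")
  y <- colSums(x[roi, , drop = FALSE])
  starts <- segment_starts(length(y), win)
  wslow <- bartlett_window(win$win_slow)
  nfft <- as.integer(pad_factor) * win$win_slow
  od <- dft_shift_order(nfft)
  acc <- numeric(nfft)
  for (s in starts) {
    z <- pad_slow(y[s:(s + win$win_slow - 1L)] * wslow, pad_factor)
    acc <- acc + (Mod(stats::fft(z))^2 / win$win_slow)[od]
  }
  f_d <- dft_freqs(nfft, iq$acq$prf)[od]
  velocity_spectrum(acc / length(starts), f_d, fc = iq$pulse$fc,
                    prf = iq$acq$prf, c = iq$acq$c, theta = iq$acq$theta,
                    win_slow = win$win_slow, method = "baseline",
                    n_segments = length(starts))
}

#' Sonogram (time-velocity power map)
#'
#' Places one short-window velocity spectrum per slow-time segment at the
#' segment's centre time, giving the familiar spectral-Doppler display.
#'
#' @inheritParams mfudsa_spectrum
#' @param method `"mfudsa"` for the 2-D multifrequency estimator or
#'   `"baseline"` for the 1-D architecture.
#' @return An object of class `sonogram`: list with `power`
#'   (velocity bins x time frames), `t` (frame centre times, s), `v`
#'   (velocity axis, m/s), `method` and `meta`.
#' @export
build_sonogram <- function(iq, win = window_spec(), method = c("mfudsa", "baseline"),
                           roi = NULL, cutoff_frac = 0.9, window_axes = "slow",
                           bw = NULL, pad_factor = 4L) {
  if (!inherits(iq, "iq_dataset")) stop("'iq' must be an iq_dataset")
  method <- match.arg(method)
  starts <- segment_starts(iq$acq$n_slow, win)
  t_axis <- (starts - 1 + (win$win_slow - 1) / 2) / iq$acq$prf

  if (method == "mfudsa") {
    upsd <- pulse_power_spectrum(make_pulse(iq$pulse))
    if (is.null(bw)) bw <- measure_fwhm_bandwidth(upsd)
    segs <- segment_pulse_lines(iq, roi = roi, win = win)
    res <- lapply(segs, function(seg) {
      mfudsa_segment(seg, iq, bw, upsd, cutoff_frac, window_axes, pad_factor)
    })
    cols <- lapply(res, `[[`, "power")
    v_axis <- res[[1L]]$v
  } else {
    x <- iq$data
    if (is.null(roi)) roi <- seq_len(nrow(x))
    y <- colSums(x[roi, , drop = FALSE])
    wslow <- bartlett_window(win$win_slow)
    nfft <- as.integer(pad_factor) * win$win_slow
    od <- dft_shift_order(nfft)
    cols <- lapply(starts, function(s) {
      z <- pad_slow(y[s:(s + win$win_slow - 1L)] * wslow, pad_factor)
      (Mod(stats::fft(z))^2 / win$win_slow)[od]
    })
    f_d <- dft_freqs(nfft, iq$acq$prf)[od]
    v_axis <- doppler_to_velocity(f_d, iq$pulse$fc, iq$acq$c, iq$acq$theta)
  }
  structure(
    list(power = do.call(cbind, cols), t = t_axis, v = v_axis,
         method = method,
         meta = list(win_slow = win$win_slow, overlap_frac = win$overlap_frac,
                     prf = iq$acq$prf, fc = iq$pulse$fc, c = iq$acq$c,
                     theta = iq$acq$theta)),
    class = "sonogram"
  )
}

#' Ridge trace of a sonogram
#'
#' Per-frame argmax velocity: the velocity bin with the largest power in
#' each time frame.
#'
#' @param sonogram A [build_sonogram()] result.
#' @return A data frame with columns `t` (s) and `v` (m/s).
#' @export
sonogram_ridge <- function(sonogram) {
  if (!inherits(sonogram, "sonogram")) stop("'sonogram' must be a sonogram")
  idx <- apply(sonogram$power, 2L, which.max)
  data.frame(t = sonogram$t, v = sonogram$v[idx])
}
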