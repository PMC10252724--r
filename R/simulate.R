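#' Acquisition specification
#'
#' Describes a pulsed-Doppler acquisition: the slow-time sampling (pulse
#' repetition frequency and number of pulse lines), the fast-time gate
#' length, beam geometry, sound speed, additive-noise level and random seed.
#'
#' @param prf Pulse repetition frequency in Hz.
#' @param n_slow Number of slow-time pulse lines (the "data length").
#' @param n_fast Fast-time samples per range gate.
#' @param theta Beam-to-flow angle in radians, `0 <= theta < pi/2`.
#' @param c Speed of sound in m/s.
#' @param snr_db Additive complex-Gaussian noise level in dB relative to the
#'   mean signal power over the gate; `Inf` for a noise-free dataset.
#' @param seed Integer random seed, or `NULL` to use the current RNG state.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(prf, n_slow, n_fast = 64, theta = 0, c = 1540,
                             snr_db = 20, seed = 1L) {
  stopifnot_scalar(prf, "prf", positive = TRUE)
  stopifnot_scalar(c, "c", positive = TRUE)
  stopifnot_scalar(theta, "theta")
  stopifnot_scalar(snr_db, "snr_db", finite = FALSE)
  if (!is.numeric(n_slow) || n_slow < 2 || n_slow != round(n_slow)) {
    stop("'n_slow' must be an integer >= 2")
  }
  if (!is.numeric(n_fast) || n_fast < 2 || n_fast != round(n_fast)) {
    stop("'n_fast' must be an integer >= 2")
  }
  if (theta < 0 || theta >= pi / 2) stop("'theta' must lie in [0, pi/2)")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L) stop("'seed' must be a single integer")
    seed <- as.integer(seed)
  }
  structure(
    list(prf = prf, n_slow = as.integer(n_slow), n_fast = as.integer(n_fast),
         theta = theta, c = c, snr_db = snr_db, seed = seed),
    class = "acquisition_spec"
  )
}

#' Simulate single-gate pulsed-Doppler IQ data
#'
#' Generates the complex baseband echo of a point scatterer following a
#' prescribed velocity waveform, insonated by the given pulse. The echo at
#' pulse line `n` is the delayed envelope times the carrier phase,
#' `s(t_f, n) = a(t_f - tau(n)) * exp(-2i*pi*fc*tau(n))`, with the two-way
#' delay advanced by the accumulated scatterer displacement,
#' `tau(n) = tau0 - (2/c) * sum_{m<n} v(m) * cos(theta) / prf`.
#' Because the envelope and the carrier share the same delay, every
#' transmitted frequency component `f_RF` acquires its own Doppler shift
#' `f_d = (2 v cos(theta) / c) * f_RF`, the ridge the multifrequency
#' estimator exploits.
#'
#' The envelope delay is wrapped modulo the gate duration so the echo never
#' leaves the fast-time gate: as the scatterer exits, a replacement enters,
#' as in real flow where blood continually crosses the sample volume. The
#' carrier phase uses the unwrapped delay, so the Doppler content is exact
#' and the gate-transit decorrelation seen by one-dimensional processing is
#' reproduced. Complex circular Gaussian noise is added to reach `snr_db`
#' relative to the mean signal power over the gate.
#'
#' @param waveform A [velocity_waveform()]; the ground truth, stored on the
#'   returned dataset.
#' @param pulse A [pulse_spec()].
#' @param acq An [acquisition_spec()].
#' @return An object of class `iq_dataset`: list with `data` (complex
#'   `n_fast x n_slow` matrix), `pulse`, `acq` and `truth`.
#' @examples
#' iq <- simulate_gate(velocity_waveform("constant", v_const = 0.2),
#'                     pulse_spec(5e6, 4),
#'                     acquisition_spec(prf = 4000, n_slow = 256, seed = 1))
#' dim(iq$data)
#' @export
simulate_gate <- function(waveform, pulse, acq) {
  if (!inherits(pulse, "pulse_spec")) stop("'pulse' must be a pulse_spec")
  if (!inherits(acq, "acquisition_spec")) stop("'acq' must be an acquisition_spec")
  n_f <- acq$n_fast
  n_s <- acq$n_slow
  fs <- pulse$fs_fast
  t_slow <- (0:(n_s - 1)) / acq$prf
  v <- waveform_velocity(waveform, t_slow, t_total = (n_s - 1) / acq$prf)
  if (max(abs(v)) * 2 * pulse$fc / acq$c >= fs / 2) {
    stop("fast-time aliasing: |v| * 2 * fc / c exceeds fs_fast / 2")
  }

  t_f <- (0:(n_f - 1)) / fs
  tau0 <- (n_f - 1) / (2 * fs) - pulse$duration / 2
  disp <- c(0, cumsum(v[-n_s])) * cos(acq$theta) / acq$prf # metres
  tau <- tau0 - 2 * disp / acq$c

  # Band-limited circular delay, synthesised in the fast-frequency domain:
  # the envelope (sampled once, centred in the gate) is delayed by applying
  # the phase ramp exp(-2i*pi*f*(tau - tau0)) to its DFT, so fractional
  # delays are exact and the echo wraps around the gate edge instead of
  # sliding out of it over long acquisitions (a new scatterer enters as one
  # leaves). Each RF column f_RF = fc + f then carries the exact phase
  # progression exp(-2i*pi*f_RF*tau(n)).
  a0 <- envelope_fun(pulse)(t_f - tau0)
  U <- stats::fft(a0)
  f_k <- dft_freqs(n_f, fs)
  ramp <- exp(-2i * pi * outer(f_k, tau - tau0))
  s <- stats::mvfft(U * ramp, inverse = TRUE) / n_f
  s <- s * matrix(exp(-2i * pi * pulse$fc * tau), n_f, n_s, byrow = TRUE)

  if (is.finite(acq$snr_db)) {
    p_sig <- mean(Mod(s)^2)
    sigma2 <- p_sig * 10^(-acq$snr_db / 10)
    noise <- with_seed(acq$seed, {
      sqrt(sigma2 / 2) * (matrix(stats::rnorm(n_f * n_s), n_f, n_s) +
                            1i * matrix(stats::rnorm(n_f * n_s), n_f, n_s))
    })
    s <- s + noise
  }
  structure(list(data = s, pulse = pulse, acq = acq, truth = waveform),
            class = "iq_dataset")
}

#' Vessel cross-section specification
#'
#' Radial sampling of a cylindrical vessel for velocity-profile and wall
#' shear stress experiments. The `"parabolic"` profile follows Poiseuille
#' flow, `v(r) = v_max * (1 - r^2/R^2)`; `"plug"` is flat at `v_max`; and
#' `"blended"` interpolates between them,
#' `v(r) = v_max * ((1 - bluntness) * (1 - r^2/R^2) + bluntness)`,
#' so `bluntness` moves the profile continuously from fully developed
#' parabolic flow (0) to plug flow (1).
#'
#' @param R Vessel radius in metres.
#' @param gate_radii Radial gate positions in metres, strictly increasing,
#'   all in `[0, R)`.
#' @param profile `"parabolic"`, `"plug"` or `"blended"`.
#' @param v_max Centreline velocity in m/s.
#' @param bluntness Blend factor in `[0, 1]` for the `"blended"` profile.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(R, gate_radii, profile = c("parabolic", "plug", "blended"),
                        v_max = 0.5, bluntness = 0) {
  stopifnot_scalar(R, "R", positive = TRUE)
  stopifnot_scalar(v_max, "v_max")
  stopifnot_scalar(bluntness, "bluntness")
  profile <- match.arg(profile)
  if (length(gate_radii) < 1L || any(gate_radii < 0) || any(gate_radii >= R)) {
    stop("gate radii must satisfy 0 <= r < R")
  }
  if (is.unsorted(gate_radii, strictly = TRUE)) {
    stop("gate radii must be strictly increasing")
  }
  if (bluntness < 0 || bluntness > 1) stop("'bluntness' must lie in [0, 1]")
  structure(
    list(R = R, gate_radii = gate_radii, n_gates = length(gate_radii),
         profile = profile, v_max = v_max, bluntness = bluntness),
    class = "vessel_spec"
  )
}

#' Radial velocity profile implied by a vessel specification
#'
#' @param vessel A [vessel_spec()].
#' @param r Radii at which to evaluate (defaults to the gate radii).
#' @return Velocities in m/s.
#' @export
vessel_velocity <- function(vessel, r = vessel$gate_radii) {
  x2 <- (r / vessel$R)^2
  b <- switch(vessel$profile, parabolic = 0, plug = 1, blended = vessel$bluntness)
  vessel$v_max * ((1 - b) * (1 - x2) + b)
}

#' Simulate IQ data for every range gate across a vessel
#'
#' Produces one [simulate_gate()] dataset per radial gate, each following a
#' constant waveform at the profile velocity of its radius (or, when
#' `waveform` is supplied, that waveform rescaled so its peak speed equals
#' the gate velocity). Gates use consecutive seed offsets from `acq$seed`
#' so their noise realisations are independent but the ensemble is
#' reproducible.
#'
#' @param vessel A [vessel_spec()].
#' @param pulse A [pulse_spec()].
#' @param acq An [acquisition_spec()]; `acq$seed` seeds gate 1, gate `j`
#'   uses `acq$seed + j - 1`.
#' @param waveform Optional [velocity_waveform()] modulating every gate.
#' @return A list of `iq_dataset` objects with attributes `radii` and
#'   `vessel`.
#' @export
simulate_vessel <- function(vessel, pulse, acq, waveform = NULL) {
  if (!inherits(vessel, "vessel_spec")) stop("'vessel' must be a vessel_spec")
  v_gate <- vessel_velocity(vessel)
  gates <- vector("list", vessel$n_gates)
  for (j in seq_len(vessel$n_gates)) {
    wf_j <- if (is.null(waveform)) {
      velocity_waveform("constant", v_const = v_gate[j])
    } else {
      t_probe <- seq(0, 10, length.out = 8192)
      peak <- max(abs(waveform_velocity(waveform, t_probe, t_total = 10)))
      scale_waveform(waveform, v_gate[j] / peak)
    }
    acq_j <- acq
    if (!is.null(acq$seed)) acq_j$seed <- acq$seed + j - 1L
    gates[[j]] <- simulate_gate(wf_j, pulse, acq_j)
  }
  structure(gates, radii = vessel$gate_radii, vessel = vessel,
            class = "vessel_dataset")
}
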