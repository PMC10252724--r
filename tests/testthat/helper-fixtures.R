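# Shared fixture builders; everything is generated in code at test time.

fix_pulse <- function(half_cycles = 4, fc = 5e6, envelope = "rectangular") {
  pulse_spec(fc, half_cycles, envelope)
}

fix_acq <- function(n_slow = 512, prf = 4000, seed = 1, snr_db = 20,
                    n_fast = 64, theta = 0) {
  acquisition_spec(prf = prf, n_slow = n_slow, n_fast = n_fast,
                   theta = theta, snr_db = snr_db, seed = seed)
}

fix_const_iq <- function(v = 0.2, ...) {
  simulate_gate(velocity_waveform("constant", v_const = v), fix_pulse(),
                fix_acq(...))
}

# Synthetic velocity spectrum on a uniform Doppler grid.
fix_vs <- function(power, prf = 4000, fc = 5e6) {
  n <- length(power)
  f_d <- seq(-prf / 2, prf / 2, length.out = n)
  velocity_spectrum(power, f_d, fc = fc, prf = prf)
}

peak_velocity <- function(vs) vs$v[which.max(vs$power)]

# Velocity bin at the estimator's slow-time resolution (not the padded
# display grid).
resolution_bin <- function(prf, win_slow, fc = 5e6) {
  doppler_to_velocity(prf / win_slow, fc)
}
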