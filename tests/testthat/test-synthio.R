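# Pulse synthesis, pulse spectra, and the IQ simulator.

test_that("pulse envelopes have the stated duration, peak and shape", {
  p <- make_pulse(pulse_spec(5e6, 4))
  expect_equal(p$duration, 4e-7) # 4 / (2 * 5 MHz)
  expect_equal(max(Mod(p$a)), 1)

  b <- make_pulse(pulse_spec(5e6, 4, "bartlett", fs_fast = 4e7))
  expect_lt(Mod(b$a[1]), 1e-12)
  expect_lt(Mod(b$a[length(b$a)]), 1e-12)
  expect_equal(which.max(Mod(b$a)), (length(b$a) + 1) %/% 2)

  expect_error(pulse_spec(5e6, 0), "half_cycles")
  expect_error(pulse_spec(5e6, 4, fs_fast = 3 * 5e6), "4 \\* fc")
  expect_error(pulse_spec(-1, 4), "positive")
})

test_that("pulse power spectrum is non-negative, symmetric and sinc-shaped", {
  ps <- pulse_power_spectrum(make_pulse(pulse_spec(5e6, 2)))
  expect_true(all(ps$power >= 0))
  expect_true(all(diff(ps$freq) > 0))
  expect_lte(ps$freq[2] - ps$freq[1], 1e4)

  # real-symmetric envelope -> symmetric spectrum (compare +f vs -f)
  ip <- which(ps$freq > 0)
  im <- match(-ps$freq[ip], ps$freq)
  ok <- !is.na(im)
  expect_equal(ps$power[ip][ok], ps$power[im[ok]], tolerance = 1e-8)

  # first null of the 2-cycle rectangular burst at 1/T from centre
  T <- 2 / (2 * 5e6)
  null_bin <- which.min(abs(ps$freq - 1 / T))
  expect_lt(ps$power[null_bin] / max(ps$power), 1e-3)

  # zero envelope -> identically zero spectrum
  z <- pulse_power_spectrum(complex(32), fs_fast = 2e7)
  expect_true(all(z$power == 0))
  expect_error(pulse_power_spectrum(complex(0), fs_fast = 2e7), "empty")
})

test_that("FWHM bandwidth follows the closed forms and halves when pulse length doubles", {
  # Gaussian spectrum: FWHM = 2.3548 sigma
  f <- seq(-5e6, 5e6, by = 1e3)
  sig <- 4e5
  bw <- measure_fwhm_bandwidth(list(freq = f, power = exp(-f^2 / (2 * sig^2))))
  expect_equal(bw, 2.3548 * sig, tolerance = 0.01)

  # rectangular 4-half-cycle 5 MHz burst: ~0.886/T = 2.215 MHz
  bw4 <- measure_fwhm_bandwidth(pulse_power_spectrum(make_pulse(pulse_spec(5e6, 4))))
  expect_equal(bw4, 0.886 / 4e-7, tolerance = 0.05)

  # doubling half cycles halves the bandwidth (+-5%)
  bw8 <- measure_fwhm_bandwidth(pulse_power_spectrum(make_pulse(pulse_spec(5e6, 8))))
  expect_equal(bw4 / bw8, 2, tolerance = 0.05)

  # strictly decreasing across the half-cycle grid (Fourier duality)
  bws <- vapply(c(2, 4, 6, 8), function(hc) {
    measure_fwhm_bandwidth(pulse_power_spectrum(make_pulse(pulse_spec(5e6, hc))))
  }, numeric(1))
  expect_true(all(diff(bws) < 0))
})

test_that("FWHM bandwidth handles ties and degenerate spectra as specified", {
  f <- 1:11
  expect_error(measure_fwhm_bandwidth(list(freq = f, power = rep(1, 11))), "no peak")
  expect_error(measure_fwhm_bandwidth(list(freq = f, power = rep(0, 11))), "no peak")

  # two equal maxima with different half-power spans: the widest wins
  p <- c(0, 1, 0, 0, 0, 0.9, 1, 0.9, 0, 0, 0)
  wide <- measure_fwhm_bandwidth(list(freq = f, power = p))
  narrow <- measure_fwhm_bandwidth(list(freq = f, power = c(0, 1, 0, rep(0, 8))))
  expect_gt(wide, narrow)

  # equal spans: tie broken toward the lower-frequency peak
  p2 <- c(0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(measure_fwhm_bandwidth(list(freq = f, power = p2)), narrow)
})

test_that("simulated gate obeys the Doppler ridge law and the zero-velocity limit", {
  # v = 0, noise-free: every pulse line identical
  iq0 <- simulate_gate(velocity_waveform("constant", v_const = 0),
                       fix_pulse(), fix_acq(n_slow = 64, snr_db = Inf))
  expect_true(all(abs(iq0$data - iq0$data[, 1]) < 1e-12))

  # constant v: slow-time spectrum at the carrier column peaks at 2 v fc / c
  iq <- simulate_gate(velocity_waveform("constant", v_const = 0.2),
                      fix_pulse(), fix_acq(n_slow = 256, snr_db = Inf))
  sp <- fft2d(iq$data, fs_fast = iq$pulse$fs_fast, prf = iq$acq$prf,
              fc = iq$pulse$fc)
  col <- which.min(abs(sp$f_rf - 5e6))
  f_hat <- sp$f_d[which.max(sp$power[col, ])]
  expect_lt(abs(f_hat - 1298.7), iq$acq$prf / 256) # one Doppler bin

  # ridge law across the band: per-column peak frequency slope = 2 v cos(theta) / c
  rows <- which(abs(sp$f_rf - 5e6) < 1.1e6)
  fpk <- vapply(rows, function(r) sp$f_d[which.max(sp$power[r, ])], numeric(1))
  slope <- stats::coef(stats::lm(fpk ~ sp$f_rf[rows]))[2]
  expect_equal(unname(slope), 2 * 0.2 / 1540, tolerance = 0.03)
})

test_that("simulator rejects invalid inputs and is seed-deterministic", {
  expect_error(
    simulate_gate(velocity_waveform("constant", v_const = 2000),
                  fix_pulse(), fix_acq(n_slow = 16)),
    "aliasing")
  expect_error(acquisition_spec(prf = 4000, n_slow = 1), "n_slow")
  expect_error(acquisition_spec(prf = 4000, n_slow = 16, theta = pi / 2), "theta")

  a <- fix_const_iq(seed = 7, n_slow = 64)
  b <- fix_const_iq(seed = 7, n_slow = 64)
  d <- fix_const_iq(seed = 8, n_slow = 64)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, d$data))
})

test_that("realised noise level matches snr_db within 1 dB", {
  wf <- velocity_waveform("constant", v_const = 0.1)
  clean <- simulate_gate(wf, fix_pulse(), fix_acq(n_slow = 1024, snr_db = Inf))
  for (snr in c(10, 20)) {
    noisy <- simulate_gate(wf, fix_pulse(), fix_acq(n_slow = 1024, snr_db = snr))
    p_sig <- mean(Mod(clean$data)^2)
    p_noise <- mean(Mod(noisy$data - clean$data)^2)
    expect_lt(abs(10 * log10(p_sig / p_noise) - snr), 1)
  }
})

test_that("vessel simulation assigns profile velocities per gate", {
  R <- 3e-3
  vp <- vessel_spec(R, c(0, R / 2, 0.9 * R), "parabolic", v_max = 0.5)
  expect_equal(vessel_velocity(vp), 0.5 * c(1, 0.75, 1 - 0.81))

  plug <- vessel_spec(R, c(0, R / 2, 0.9 * R), "plug", v_max = 0.5)
  expect_equal(vessel_velocity(plug), rep(0.5, 3))

  # blended profile interpolates between the two
  half <- vessel_spec(R, c(0, R / 2), "blended", v_max = 0.5, bluntness = 0.5)
  expect_equal(vessel_velocity(half), 0.5 * (0.5 * c(1, 0.75) + 0.5))

  expect_error(vessel_spec(R, c(0, R)), "r < R")
  expect_error(vessel_spec(R, c(1e-3, 1e-3)), "increasing")

  gates <- simulate_vessel(vp, fix_pulse(), fix_acq(n_slow = 32))
  expect_length(gates, 3)
  expect_equal(attr(gates, "radii"), vp$gate_radii)
  truths <- vapply(gates, function(g) g$truth$params$v_const, numeric(1))
  expect_equal(truths, vessel_velocity(vp))
  # distinct seeds -> distinct noise
  expect_false(identical(gates[[1]]$data, gates[[2]]$data))
})

test_that("pulsatile waveform is positive, periodic and scaled to its peak", {
  wf <- velocity_waveform("pulsatile", v_peak = 0.45)
  t <- seq(0, 1, length.out = 2001)
  v <- waveform_velocity(wf, t)
  expect_equal(max(v), 0.45, tolerance = 1e-3)
  expect_true(all(v > 0))
  expect_equal(waveform_velocity(wf, 0.1), waveform_velocity(wf, 0.1 + 0.5),
               tolerance = 1e-12)
})
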