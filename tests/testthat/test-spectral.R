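# Windowing, 2-D transform, low-pass, spectral scaling, and the two
# estimation pipelines.

test_that("segmentation produces the documented hop and segment count", {
  x <- matrix(0 + 0i, 4, 1000)
  segs <- segment_pulse_lines(x, win = window_spec(128, 0.75))
  expect_equal(attr(segs, "hop"), 32L)
  expect_length(segs, floor((1000 - 128) / 32) + 1) # 28
  expect_equal(dim(segs[[1]]), c(4L, 128L))

  one <- segment_pulse_lines(x, win = window_spec(1000, 0.5))
  expect_length(one, 1)

  roi <- segment_pulse_lines(x, roi = 2:3, win = window_spec(256, 0))
  expect_equal(nrow(roi[[1]]), 2L)

  expect_error(segment_pulse_lines(x, roi = integer(0)), "empty")
  expect_error(segment_pulse_lines(x, win = window_spec(1024, 0)), "exceeds")
})

test_that("Bartlett windowing matches the triangular definition and composes", {
  expect_equal(apply_bartlett(rep(1 + 0i, 5)), c(0, 0.5, 1, 0.5, 0) + 0i)
  m <- matrix(1 + 0i, 5, 5)
  w <- c(0, 0.5, 1, 0.5, 0)
  expect_equal(apply_bartlett(m, "both"), outer(w, w) + 0i)
  # windowing twice = windowing by the squared window
  expect_equal(apply_bartlett(apply_bartlett(m, "slow"), "slow"),
               t(t(m) * w^2))
})

test_that("fft2d satisfies Parseval and localises tones correctly", {
  set.seed(42)
  x <- matrix(complex(real = rnorm(64 * 32), imaginary = rnorm(64 * 32)), 64, 32)
  sp <- fft2d(x, fs_fast = 2e7, prf = 4000, fc = 5e6)
  expect_equal(sum(sp$power), sum(Mod(x)^2), tolerance = 1e-9)
  expect_true(all(sp$power >= 0))
  expect_true(all(diff(sp$f_rf) > 0))
  expect_true(all(diff(sp$f_d) > 0))
  expect_true(all(sp$f_d > -2000) && max(sp$f_d) == 2000) # (-prf/2, prf/2]

  # constant matrix: all power in the (fc, 0 Hz) bin
  dc <- fft2d(matrix(1 + 0i, 8, 8), fs_fast = 2e7, prf = 4000, fc = 5e6)
  hot <- which(dc$power > 1e-9, arr.ind = TRUE)
  expect_equal(nrow(hot), 1L)
  expect_equal(dc$f_rf[hot[1]], 5e6)
  expect_equal(dc$f_d[hot[2]], 0)

  # slow-time complex exponential at f0: single Doppler column
  f0 <- 1000
  tone <- matrix(exp(2i * pi * f0 * (0:31) / 4000), 8, 32, byrow = TRUE)
  tsp <- fft2d(tone, fs_fast = 2e7, prf = 4000, fc = 5e6)
  expect_equal(tsp$f_d[which.max(colSums(tsp$power))], f0)

  expect_error(fft2d(matrix(0 + 0i, 1, 8), 2e7, 4000, 5e6), "degenerate")
})

test_that("PRF low-pass keeps the passband and removes the band edge", {
  set.seed(1)
  x <- matrix(complex(real = rnorm(8 * 64), imaginary = rnorm(8 * 64)), 8, 64)
  sp <- fft2d(x, fs_fast = 2e7, prf = 4000, fc = 5e6)
  lp <- lowpass_prf(sp, 0.9)
  inner <- abs(sp$f_d) <= 0.8 * 0.9 * 2000
  expect_equal(lp$power[, inner], sp$power[, inner])
  edge <- abs(sp$f_d) >= 0.9 * 2000
  expect_true(all(lp$power[, edge] == 0))

  # white spectrum: output power ~ input power x mean filter gain (+-2%)
  gain <- mfudsa:::lowpass_gain(sp$f_d, 0.9 * 2000)
  expect_equal(sum(lp$power) / sum(sp$power), mean(gain), tolerance = 0.02)
})

test_that("spectral scaling reproduces brute-force integration of the averaging equation", {
  # flat unit spectrum, flat unit weight, 16x16 grid
  n <- 16
  sp <- structure(list(
    power = matrix(1, n, n),
    f_rf = 5e6 + seq(-0.75e6, 0.75e6, length.out = n),
    f_d = seq(-2000, 2000, length.out = n),
    fc = 5e6, prf = 4000, fs_fast = 2e7, lp_cutoff = NULL),
    class = "spectrum2d")
  out <- spectral_scale_average(sp, bw = 1e6)

  # independent brute-force rectangle-rule-free oracle: direct double loop
  rows <- which(sp$f_rf >= 5e6 - 5e5 & sp$f_rf <= 5e6 + 5e5)
  w <- mfudsa:::trapz_weights(sp$f_rf[rows])
  oracle <- vapply(seq_along(sp$f_d), function(j) {
    acc <- 0
    for (i in seq_along(rows)) {
      fd_scaled <- sp$f_d[j] * sp$f_rf[rows[i]] / 5e6
      val <- if (fd_scaled < min(sp$f_d) || fd_scaled > max(sp$f_d)) 0 else {
        stats::approx(sp$f_d, sp$power[rows[i], ], xout = fd_scaled)$y
      }
      acc <- acc + w[i] * val
    }
    acc / sum(w)
  }, numeric(1))
  expect_equal(out$power, oracle, tolerance = 1e-12)

  # interior bins are exactly flat at unit level
  interior <- abs(sp$f_d) < 1500
  expect_equal(out$power[interior], rep(1, sum(interior)))

  # zero spectrum -> zero output
  sp0 <- sp
  sp0$power[] <- 0
  expect_true(all(spectral_scale_average(sp0, bw = 1e6)$power == 0))

  expect_error(spectral_scale_average(sp, bw = 1e8), "span")
})

test_that("Doppler-velocity conversion follows the Doppler equation", {
  expect_equal(doppler_to_velocity(0, 5e6), 0)
  expect_equal(doppler_to_velocity(1298.7, 5e6), 0.2, tolerance = 1e-4)
  # Nyquist velocity at PRF 4 kHz is below a 40 cm/s cosine peak
  v_nyq <- doppler_to_velocity(2000, 5e6)
  expect_equal(v_nyq, 0.3080, tolerance = 1e-3)
  expect_lt(v_nyq, 0.40)
  expect_error(doppler_to_velocity(100, 5e6, theta = pi / 2), "cosine")
})

test_that("both estimators locate a constant velocity within one resolution bin", {
  win <- window_spec(128, 0.75)
  iq <- fix_const_iq(v = 0.2, n_slow = 1024, seed = 3)
  bin <- resolution_bin(4000, 128)
  expect_lt(abs(peak_velocity(mfudsa_spectrum(iq, win = win)) - 0.2), bin)
  expect_lt(abs(peak_velocity(baseline_1d_spectrum(iq, win = win)) - 0.2), bin)

  iq0 <- fix_const_iq(v = 0, n_slow = 1024, seed = 3)
  expect_lt(abs(peak_velocity(mfudsa_spectrum(iq0, win = win))), bin)
})

test_that("opposite velocities give mirrored peaks of matching power", {
  win <- window_spec(128, 0.75)
  pos <- mfudsa_spectrum(fix_const_iq(v = 0.15, n_slow = 1024, seed = 5), win = win)
  neg <- mfudsa_spectrum(fix_const_iq(v = -0.15, n_slow = 1024, seed = 5), win = win)
  expect_equal(peak_velocity(pos), -peak_velocity(neg), tolerance = 0.02)
  expect_equal(max(pos$power) / max(neg$power), 1, tolerance = 0.1)
})

test_that("scaling collapses the multifrequency ridge (narrower than the unscaled marginal)", {
  # noise-free broadband dataset, BW/fc = 0.89 > 0.2; v chosen so the
  # per-column peaks of the unscaled marginal overlap into one smeared hill
  iq <- simulate_gate(velocity_waveform("constant", v_const = 0.05),
                      fix_pulse(2), fix_acq(n_slow = 512, snr_db = Inf))
  win <- window_spec(128, 0.75)
  vs2 <- mfudsa_spectrum(iq, win = win)

  # unscaled marginal: trapezoid-weighted sum over the same RF band, no scaling
  upsd <- pulse_power_spectrum(make_pulse(iq$pulse))
  bw <- measure_fwhm_bandwidth(upsd)
  segs <- segment_pulse_lines(iq, win = win)
  acc <- NULL
  for (seg in segs) {
    seg <- apply_bartlett(seg, "slow")
    sp <- lowpass_prf(fft2d(mfudsa:::pad_slow(seg, 4L), 2e7, 4000, 5e6), 0.9)
    rows <- which(sp$f_rf >= 5e6 - bw / 2 & sp$f_rf <= 5e6 + bw / 2)
    w <- mfudsa:::trapz_weights(sp$f_rf[rows])
    marg <- colSums(sp$power[rows, ] * w) / sum(w)
    acc <- if (is.null(acc)) marg else acc + marg
  }
  marginal <- velocity_spectrum(acc / length(segs), vs2$f_d, fc = 5e6, prf = 4000)
  expect_lt(fwhm_of_spectrum(vs2), fwhm_of_spectrum(marginal))
})

test_that("the 2-D estimator reduces to the 1-D baseline in the narrowband limit", {
  # long pulse -> bandwidth a few RF bins wide; larger gate keeps it resolvable
  iq <- simulate_gate(velocity_waveform("constant", v_const = 0.2),
                      pulse_spec(5e6, 30), fix_acq(n_slow = 512, n_fast = 256,
                                                   snr_db = Inf))
  win <- window_spec(128, 0.75)
  a <- mfudsa_spectrum(iq, win = win)
  b <- baseline_1d_spectrum(iq, win = win)
  pa <- a$power / max(a$power)
  pb <- b$power / max(b$power)
  keep <- abs(a$f_d) <= 0.8 * 2000 # away from the low-pass transition
  expect_lt(max(abs(pa[keep] - pb[keep])), 0.05)
})

test_that("pure noise yields an approximately flat baseline spectrum", {
  set.seed(11)
  x <- matrix(complex(real = rnorm(64 * 512), imaginary = rnorm(64 * 512)), 64, 512)
  iq <- structure(list(data = x, pulse = fix_pulse(),
                       acq = fix_acq(n_slow = 512)), class = "iq_dataset")
  vs <- baseline_1d_spectrum(iq, win = window_spec(128, 0.75))
  expect_lt(max(vs$power) / mean(vs$power), 3)
})

test_that("sonograms trace constant, ramping and aliased waveforms", {
  win <- window_spec(128, 0.75)
  bin <- resolution_bin(4000, 128)

  son <- build_sonogram(fix_const_iq(v = 0.2, n_slow = 1024, seed = 2), win = win)
  ridge <- sonogram_ridge(son)
  expect_equal(ncol(son$power), nrow(ridge))
  expect_true(all(abs(ridge$v - 0.2) < bin)) # horizontal ridge

  # linear ramp: ridge is monotone increasing overall
  ramp <- simulate_gate(velocity_waveform("linear", v_start = -0.2, v_end = 0.2),
                        fix_pulse(), fix_acq(n_slow = 4000, prf = 5000, seed = 2))
  rr <- sonogram_ridge(build_sonogram(ramp, win = win))
  expect_gt(stats::cor(rr$t, rr$v), 0.99)

  # cosine at PRF 7 kHz: extremes recovered, no wrap (v_nyq = 0.539)
  cosw <- velocity_waveform("cosine", v_peak = 0.4, period = 1)
  iq7 <- simulate_gate(cosw, fix_pulse(), fix_acq(n_slow = 7500, prf = 7000, seed = 2))
  r7 <- sonogram_ridge(build_sonogram(iq7, win = win))
  bin7 <- resolution_bin(7000, 128)
  expect_lt(abs(max(r7$v) - 0.4), bin7)
  expect_lt(abs(min(r7$v) + 0.4), bin7)

  # same waveform at PRF 4 kHz aliases: the ridge wraps to v - 2 v_nyq
  iq4 <- simulate_gate(cosw, fix_pulse(), fix_acq(n_slow = 2000, prf = 4000, seed = 2))
  r4 <- sonogram_ridge(build_sonogram(iq4, win = win))
  v_nyq <- doppler_to_velocity(2000, 5e6)
  expect_true(all(abs(r4$v) <= v_nyq + bin))
  # velocity information is lost where |v| exceeds the Nyquist velocity
  i_peak <- which.max(waveform_velocity(iq4$truth, r4$t))
  expect_gt(abs(r4$v[i_peak] - 0.4 * cos(2 * pi * r4$t[i_peak])), 0.05)
})

test_that("estimation pipelines are deterministic for a fixed seed", {
  a <- mfudsa_spectrum(fix_const_iq(seed = 9, n_slow = 512))
  b <- mfudsa_spectrum(fix_const_iq(seed = 9, n_slow = 512))
  expect_identical(a$power, b$power)
})
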