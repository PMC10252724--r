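---
title: "Multifrequency ultrafast Doppler spectral analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifrequency ultrafast Doppler spectral analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfudsa)
```

## The estimation problem

Pulsed-wave Doppler ultrasound estimates blood velocity from the phase
progression of echoes across successive transmissions. A scatterer moving at
velocity $v$ along a beam at angle $\theta$ shifts a transmitted frequency
$f_{RF}$ by

$$f_d = \frac{2 v \cos\theta}{c}\, f_{RF}.$$

Conventional spectral Doppler attributes all received energy to the carrier
$f_c$, discarding the fact that a finite pulse transmits a whole band of
frequencies, each carrying an independent estimate of the same velocity. The
two-dimensional multifrequency estimator implemented here recovers those
estimates: a 2-D DFT of the fast-time $\times$ slow-time IQ matrix yields a
power distribution $P(f_{RF}, f_d)$ in which a moving target appears as a
ridge of slope $2 v \cos\theta / c$. Rescaling each RF column's Doppler axis
by $f_{RF}/f_c$ aligns the per-frequency spectra, which are then averaged
over the transmitted band:

$$\hat P^{MF}(f_d) \;=\;
\frac{\int_{f_c-BW/2}^{f_c+BW/2} P\!\left(f_{RF},\, f_d\, f_{RF}/f_c\right)\, df_{RF}}
     {\int_{f_c-BW/2}^{f_c+BW/2} \left|U(f_{RF}-f_c)\right|^2 df_{RF}},$$

where $|U|^2$ is the power spectrum of the pulse's complex envelope and $BW$
its full width at half maximum. The pipeline (`mfudsa_spectrum()`) is:
slow-time segmentation, Bartlett windowing, 2-D DFT, a Doppler-axis low-pass
that suppresses energy approaching the pulse repetition frequency, spectral
scaling/averaging, and Welch-style averaging of the per-segment spectra. The
matched one-dimensional reference (`baseline_1d_spectrum()`) sums the range
gate coherently and applies the identical segmentation, windowing and
averaging to the resulting slow-time series.

The narrowbandness of a pulse is summarised by the quality factor
$Q = (f_c/BW)\ln 2$ (`q_factor()`); shorter pulses have lower $Q$ and more
independent frequencies available for averaging.

## The synthetic-data generator

`simulate_gate()` generates the baseband echo of a point target following a
prescribed velocity waveform:

$$s(t_f, n) = a\!\left(t_f - \tau(n)\right)\, e^{-2\pi i f_c \tau(n)},
\qquad
\tau(n) = \tau_0 - \frac{2\cos\theta}{c\,\mathrm{PRF}} \sum_{m<n} v(m),$$

with complex circular Gaussian noise added to reach `snr_db` relative to the
mean signal power over the gate. Because the delay appears in both the
envelope and the carrier phase, every transmitted frequency acquires its own
Doppler shift and the 2-D spectrum carries the exact multifrequency ridge.
Two numerical choices matter:

* **Circular delay wrap.** Over long acquisitions the accumulated
  displacement far exceeds the gate depth (the ±20 cm/s ramp moves the
  target ~15 cm against a ~2.5 mm gate), so the envelope delay is wrapped
  modulo the gate duration: as the echo slides out of one edge it re-enters
  at the other, emulating the continuous replacement of scatterers in
  flowing blood while keeping the phase history exact.
* **Band-limited synthesis.** The delay is applied in the fast-frequency
  domain as a phase ramp on the envelope's DFT. Evaluating a discontinuous
  envelope on the sample grid at fractional delays instead produces a
  broadband pedestal roughly 38 dB below the peak that dominates the
  spectral floor and corrupts any SNR measurement.

What the generator deliberately omits: diffuse speckle (a random scatterer
ensemble and its transit-time decorrelation), attenuation, wall clutter, and
beamforming. Passing tests therefore demonstrate correctness of the
estimation chain on ridge-exact signals with calibrated white noise, not
performance on tissue-realistic texture. The pulsatile waveform is a
three-harmonic, always-positive template scaled to a 0.45 m/s peak (a
paediatric umbilical / renal-artery scale) with a 0.5 s period (120 beats
per minute), chosen because the reference waveform is not tabulated;
`simulate_vessel()` assigns per-gate amplitudes from parabolic, plug or
blended radial profiles with per-gate seed offsets.

Default acquisition settings: `n_fast = 64` samples at `fs_fast = 4 fc`
(a 2.5 mm gate at 5 MHz), `snr_db = 20`. Neither is dictated by the physics;
both are exposed in `acquisition_spec()`.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `half_cycles` | 4 | half cycles | pulse length; sets $BW \approx 0.886\,(2 f_c/\mathrm{hc})$ and $Q$ |
| `fs_fast` | $4 f_c$ | Hz | fast-time rate; with `n_fast` sets the gate depth and RF bin spacing |
| `win_slow` | 128 | pulse lines | slow-time window; sets velocity resolution $\Delta v = c\,\mathrm{PRF}/(2 f_c\, \mathrm{win})$ |
| `overlap_frac` | 0.75 | — | Welch segment overlap |
| `cutoff_frac` | 0.9 | — | Doppler low-pass edge as a fraction of PRF/2 |
| `pad_factor` | 4 | — | slow-time zero padding of the Doppler grid |
| `mu` | 4.0e-3 | Pa s | blood / blood-mimic dynamic viscosity for WSS |
| `n_fit` | 3 | gates | near-wall gates in the shear-rate fit |

The window length and overlap are analysis choices (the Welch trade-off
between variance and time resolution); 128 lines at 75% overlap give a
velocity resolution bin of 0.48 cm/s at PRF 4 kHz and 5 MHz.

## Numerical choices

* **Windowing axis.** The Bartlett taper is applied to slow time by
  default (`window_axes` flag). The echo envelope is compactly supported
  inside the gate, so fast-time truncation creates no sidelobes; tapering
  fast time would only widen each RF column's response and correlate
  neighbouring RF bins, weakening the multifrequency average.
* **Quadrature.** The scaling integral uses linear interpolation along each
  column's Doppler axis (hard zero outside support) and trapezoidal
  integration over $f_{RF}$; its error vanishes under grid refinement. The
  slow-time spectra are zero-padded fourfold before scaling: without the
  padding, power-domain linear interpolation of a scalloped spectrum biases
  the aligned peak low by up to ~3 dB. Padding refines the display grid
  only; the resolution bin remains $\mathrm{PRF}/\mathrm{win}$, and all
  "within one velocity bin" statements refer to that resolution bin.
* **Low-pass.** The PRF filter is a Doppler-axis mask at
  `cutoff_frac * PRF/2` with a raised-cosine taper over the top 10% of the
  passband; the passband interior is untouched and the filter is applied
  before scaling, following the processing order of the chain.
* **Axis conventions.** Doppler axes lie in $(-\mathrm{PRF}/2,
  +\mathrm{PRF}/2]$; positive velocity means flow toward the transducer;
  aliased content wraps with no unwrapping attempted.
* **Ties and degenerate inputs.** Bandwidth measurement takes the widest
  contiguous half-power span of the global peak, ties broken toward lower
  frequency; flat spectra raise a no-peak error; paired comparisons with
  identical sequences return $t = 0$, $p = 1$, while constant non-zero
  differences are rejected as degenerate.

## Quantifying estimator performance

Velocity resolution is the full width at half maximum of the main velocity
peak, measured at half of (peak − floor) with the median spectrum power as
the floor and sub-bin interpolation on both flanks (`fwhm_of_spectrum()`).

SNR needs more care, and `snr_of_spectrum()` offers two statistics. The
`"contrast"` statistic (peak over mean noise-floor power, the default) is
the intuitive reading of a displayed spectrum, but it is mathematically
blind to the benefit of multifrequency averaging: averaging $K$ independent
RF columns leaves the expected floor level unchanged and reduces only its
variance. The `"detectability"` statistic, (peak − median floor) / MAD
(floor), measures the peak against the floor's fluctuation and therefore
registers the $\sqrt{K}$ averaging gain; it is the statistic
`ratio_experiment()` uses for the 2-D/1-D comparison, consistent with the
variance-reduction rationale of multifrequency spectral averaging. Robust
(median/MAD) floor statistics are used because a handful of bins carrying
deterministic window-sidelobe leakage near the signal exclusion zone would
otherwise dominate both the mean and the standard deviation at moderate
noise levels.

Two facts about the matched comparison are worth stating plainly, because
they bound what any simulation of this architecture can show. First, the
coherent range-gate sum collapses the transmitted band: while the echo lies
inside the gate, the fast-time integral of the delayed envelope is
delay-independent, so the 1-D baseline's spectrum is as narrow as the
analysis window allows and suffers no multifrequency broadening. Second,
the 2-D output carries a small width penalty of order $1 + (BW/2f_c)^2/3$
from the scaling's axis compression. Consequently, on this signal model the
2-D estimator's advantage appears as a floor-smoothing (detectability) gain
of roughly $0.6\sqrt{BW \cdot T_{gate}}$ — about a factor 2 at two half
cycles with the default 64-sample gate — and as a resolution ratio slightly
below unity, rather than the larger gains achievable on hardware data where
the one-dimensional chain is additionally penalised by speckle
decorrelation and instrument noise. The inverse relationship between $Q$
and the SNR gain across the pulse-length grid is reproduced.

## Wall shear stress

`wall_shear_rate()` fits a least-squares line to the `n_fit` gates nearest
the wall and evaluates the (negated) slope; no zero-velocity wall point is
imposed because only intraluminal measurements exist. `wss_gradient()`
multiplies by the viscosity; `wss_parabolic()` is the Poiseuille shortcut
$2\mu V_{max}/R$. On an exactly parabolic profile the secant fit
underestimates the wall gradient by a factor $\bar r / R$ of the fitted
gates, so the two methods agree to 1% only when the gates sit within ~1.5%
of the wall — an intrinsic property of gate-limited sampling, not a defect.
Per-gate velocities are taken as the spectral peak (mode) of each gate's
velocity spectrum. Blunting the profile from parabolic toward plug at fixed
centreline velocity lowers the gradient-method WSS monotonically in the
blended-profile family.

`compare_conditions()` applies a two-sided paired t-test to
position-matched WSS samples.

## Problem sizes used in validation

The packaged validation suite runs a 45-replicate sweep over pulse lengths
\{2, 4, 6, 8\} half cycles at 2048 pulse lines each, recovers a
15,000-line linear ramp at PRF 5 kHz and a 21,000-line ±40 cm/s cosine at
PRF 7 kHz, and checks aliasing of the same cosine at PRF 4 kHz; these sizes
exercise every code path at full fidelity while keeping a complete run in
the minutes range on a single core.

## Known limitations

* Single-target, speckle-free signal model (see above); no clutter filter
  beyond the PRF low-pass, no beamforming, no attenuation.
* The open `.iqz` container is the only ingest path; proprietary scanner
  formats must be converted externally.
* Velocity extraction per gate is the spectral mode; percentile-based
  envelope tracking is not implemented.
* No unwrapping of aliased sonograms.
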