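#' Ground-truth velocity waveforms
#'
#' Constructs the slow-time velocity waveform a simulated scatterer follows.
#' Four kinds are supported:
#'
#' * `"constant"`: `v_const` at all times.
#' * `"linear"`: affine ramp from `v_start` to `v_end`. When `duration` is
#'   `NULL` the ramp spans the full acquisition it is evaluated over.
#' * `"cosine"`: zero-mean `v_peak * cos(2*pi*t/period)`.
#' * `"pulsatile"`: an always-forward three-harmonic arterial template
#'   scaled so its peak equals `v_peak` (default 0.45 m/s, a paediatric
#'   umbilical / renal-artery scale peak velocity).
#'
#' @param kind Waveform kind.
#' @param v_const Constant velocity (m/s).
#' @param v_start,v_end Ramp endpoints (m/s).
#' @param v_peak Peak velocity (m/s) for the cosine and pulsatile kinds.
#' @param period Modulation period in seconds (cosine default 1 s,
#'   pulsatile default 0.5 s, i.e. 120 beats per minute).
#' @param duration Ramp duration in seconds for the linear kind, or `NULL`
#'   to span the acquisition.
#' @return An object of class `velocity_waveform`.
#' @examples
#' wf <- velocity_waveform("cosine", v_peak = 0.4, period = 1)
#' waveform_velocity(wf, c(0, 0.25, 0.5))
#' @export
velocity_waveform <- function(kind = c("constant", "linear", "cosine", "pulsatile"),
                              v_const = 0.2, v_start = -0.2, v_end = 0.2,
                              v_peak = 0.45, period = NULL, duration = NULL) {
  kind <- match.arg(kind)
  params <- switch(kind,
    constant = {
      stopifnot_scalar(v_const, "v_const")
      list(v_const = v_const)
    },
    linear = {
      stopifnot_scalar(v_start, "v_start")
      stopifnot_scalar(v_end, "v_end")
      if (!is.null(duration)) stopifnot_scalar(duration, "duration", positive = TRUE)
      list(v_start = v_start, v_end = v_end, duration = duration)
    },
    cosine = {
      stopifnot_scalar(v_peak, "v_peak")
      if (is.null(period)) period <- 1
      stopifnot_scalar(period, "period", positive = TRUE)
      list(v_peak = v_peak, period = period)
    },
    pulsatile = {
      stopifnot_scalar(v_peak, "v_peak")
      if (is.null(period)) period <- 0.5
      stopifnot_scalar(period, "period", positive = TRUE)
      list(v_peak = v_peak, period = period)
    }
  )
  structure(list(kind = kind, params = params), class = "velocity_waveform")
}

# Raw three-harmonic arterial template on phase u in [0, 1); strictly
# positive, systolic peak near u = 0.25.
pulsatile_template <- function(u) {
  0.5 + 0.35 * sin(2 * pi * u) + 0.12 * sin(4 * pi * u - 0.6) +
    0.05 * sin(6 * pi * u - 1.2)
}

#' Evaluate a velocity waveform at given times
#'
#' @param waveform A [velocity_waveform()].
#' @param t Times in seconds.
#' @param t_total Acquisition duration in seconds; used by the linear kind
#'   when it was built without an explicit `duration`.
#' @return Velocities in m/s.
#' @export
waveform_velocity <- function(waveform, t, t_total = NULL) {
  if (!inherits(waveform, "velocity_waveform")) {
    stop("'waveform' must be a velocity_waveform")
  }
  p <- waveform$params
  v <- switch(waveform$kind,
    constant = rep(p$v_const, length(t)),
    linear = {
      d <- p$duration
      if (is.null(d)) d <- t_total
      if (is.null(d) || d <= 0) stop("linear waveform needs a positive duration")
      p$v_start + (p$v_end - p$v_start) * pmin(pmax(t / d, 0), 1)
    },
    cosine = p$v_peak * cos(2 * pi * t / p$period),
    pulsatile = {
      u <- (t / p$period) %% 1
      h <- pulsatile_template(u)
      hmax <- max(pulsatile_template(seq(0, 1, length.out = 4096)))
      p$v_peak * h / hmax
    }
  )
  if (any(!is.finite(v))) stop("waveform produced non-finite velocities")
  v
}

# Return a copy of the waveform with velocities scaled by a constant factor
# (used to assign per-gate amplitudes across a vessel cross-section).
scale_waveform <- function(waveform, factor) {
  p <- waveform$params
  switch(waveform$kind,
    constant = velocity_waveform("constant", v_const = p$v_const * factor),
    linear = velocity_waveform("linear", v_start = p$v_start * factor,
                               v_end = p$v_end * factor, duration = p$duration),
    cosine = velocity_waveform("cosine", v_peak = p$v_peak * factor,
                               period = p$period),
    pulsatile = velocity_waveform("pulsatile", v_peak = p$v_peak * factor,
                                  period = p$period)
  )
}
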