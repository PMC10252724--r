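# Wall shear stress estimation from radial velocity profiles.

#' Radial velocity profile
#'
#' Velocity samples across a vessel lumen at known radial positions, with
#' the vessel radius and fluid viscosity needed for shear computations.
#'
#' @param r Radial gate positions in metres, strictly increasing, all in
#'   `[0, R)`. At least 3 gates.
#' @param v Velocity estimates per gate (m/s).
#' @param R Vessel radius (m).
#' @param mu Dynamic viscosity (Pa s); 4.0e-3 is typical of blood and
#'   blood-mimicking fluids.
#' @return An object of class `velocity_profile`.
#' @export
velocity_profile <- function(r, v, R, mu = 4.0e-3) {
  stopifnot_scalar(R, "R", positive = TRUE)
  stopifnot_scalar(mu, "mu", positive = TRUE)
  if (length(r) != length(v) || length(r) < 3L) {
    stop("need at least 3 gates with matching radii and velocities")
  }
  if (any(r < 0) || any(r >= R)) stop("gate radii must satisfy 0 <= r < R")
  if (is.unsorted(r, strictly = TRUE)) stop("gate radii must be strictly increasing")
  if (any(!is.finite(v))) stop("velocities must be finite")
  structure(list(r = r, v = v, R = R, mu = mu), class = "velocity_profile")
}

#' Build a velocity profile from per-gate spectra
#'
#' Takes the spectral-peak (mode) velocity of each gate's velocity spectrum
#' as that gate's velocity estimate.
#'
#' @param spectra List of `velocity_spectrum` objects, one per gate.
#' @param radii Radial positions of the gates (m).
#' @param R Vessel radius (m).
#' @param mu Dynamic viscosity (Pa s).
#' @return A [velocity_profile()].
#' @export
profile_from_gates <- function(spectra, radii, R, mu = 4.0e-3) {
  if (length(spectra) != length(radii)) stop("one spectrum per radius required")
  v <- vapply(seq_along(spectra), function(j) {
    vs <- spectra[[j]]
    if (max(vs$power) <= mean(vs$power)) {
      stop(sprintf("gate %d has no detectable spectral peak", j))
    }
    vs$v[which.max(vs$power)]
  }, numeric(1))
  velocity_profile(radii, v, R, mu)
}

#' Wall shear rate by near-wall linear fit
#'
#' Fits a straight line by least squares to the `n_fit` gates closest to
#' the wall (largest radii) and returns the negated slope, the velocity
#' gradient magnitude extrapolated to `r = R`. No zero-velocity wall point
#' is imposed: only measurements inside the lumen enter the fit.
#'
#' @param profile A [velocity_profile()].
#' @param n_fit Number of near-wall gates in the fit (>= 2).
#' @return Wall shear rate in 1/s (positive for forward flow decreasing
#'   toward the wall).
#' @export
wall_shear_rate <- function(profile, n_fit = 3) {
  if (!inherits(profile, "velocity_profile")) stop("'profile' must be a velocity_profile")
  if (n_fit < 2) stop("'n_fit' must be at least 2")
  n <- length(profile$r)
  n_fit <- min(as.integer(n_fit), n)
  idx <- order(profile$r, decreasing = TRUE)[seq_len(n_fit)]
  r <- profile$r[idx]
  v <- profile$v[idx]
  if (stats::sd(r) == 0) stop("degenerate fit: identical gate radii")
  fit <- stats::lm.fit(cbind(1, r), v)
  -unname(fit$coefficients[2L])
}

#' Wall shear stress by the velocity-gradient method
#'
#' `WSS = mu * |dV/dr|` at the wall, with the gradient from
#' [wall_shear_rate()]'s near-wall linear fit. Forward flow (velocity
#' decreasing toward the wall) yields positive stress.
#'
#' @inheritParams wall_shear_rate
#' @param position Longitudinal station label carried into reports.
#' @return An object of class `wss_result`: list with `wss` (Pa),
#'   `method`, `shear_rate` (1/s) and `position`.
#' @export
wss_gradient <- function(profile, n_fit = 3, position = NA_character_) {
  sr <- wall_shear_rate(profile, n_fit)
  structure(list(wss = profile$mu * sr, method = "gradient",
                 shear_rate = sr, position = position),
            class = "wss_result")
}

#' Wall shear stress by the parabolic (Poiseuille) method
#'
#' `WSS = 2 * mu * v_max / R`: valid for fully developed laminar flow in a
#' rigid tube, where the centreline velocity alone determines the wall
#' gradient.
#'
#' @param v_max Centreline (peak) velocity in m/s.
#' @param mu Dynamic viscosity (Pa s).
#' @param R Vessel radius (m).
#' @param position Longitudinal station label.
#' @return An object of class `wss_result`.
#' @examples
#' wss_parabolic(0.5, mu = 4e-3, R = 3e-3)$wss # 1.333 Pa
#' @export
wss_parabolic <- function(v_max, mu = 4.0e-3, R, position = NA_character_) {
  stopifnot_scalar(v_max, "v_max")
  stopifnot_scalar(mu, "mu", positive = TRUE)
  if (!is.numeric(R) || length(R) != 1L || R <= 0) stop("'R' must be positive")
  wss <- 2 * mu * v_max / R
  structure(list(wss = wss, method = "parabolic",
                 shear_rate = 2 * v_max / R, position = position),
            class = "wss_result")
}

#' Paired comparison of wall shear stress between two conditions
#'
#' Two-sided paired t-test on position-matched WSS samples. Identical
#' sequences return `t = 0`, `p = 1`; a constant non-zero difference has
#' no variance to test against and raises an error.
#'
#' @param wss_a,wss_b Numeric vectors of equal length (>= 3), paired by
#'   position.
#' @return A list with `t`, `dof`, `p` and `mean_diff` (mean of a - b).
#' @export
compare_conditions <- function(wss_a, wss_b) {
  if (length(wss_a) != length(wss_b)) stop("paired samples must have equal length")
  if (length(wss_a) < 3L) stop("need at least 3 pairs")
  d <- wss_a - wss_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, dof = length(d) - 1L, p = 1, mean_diff = 0))
    }
    stop("zero-variance differences: paired t-test is degenerate")
  }
  ht <- stats::t.test(wss_a, wss_b, paired = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}
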