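# Internal numeric helpers shared across modules.

# DFT bin frequencies in natural (unshifted) order, Nyquist assigned to the
# positive side so the shifted axis lies in (-fs/2, +fs/2].
dft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) * fs / n
}

# Reorder a vector (or matrix rows/cols) from natural DFT order to a strictly
# increasing frequency axis under the (-fs/2, fs/2] convention.
dft_shift_order <- function(n) {
  order(dft_freqs(n, 1))
}

# Linear interpolation of y (sampled on the uniform grid x0 + (0:(n-1))*dx)
# at arbitrary points xout; hard zero outside the sampled support.
interp_uniform <- function(y, x0, dx, xout) {
  n <- length(y)
  p <- (xout - x0) / dx
  i <- floor(p)
  f <- p - i
  lo <- i + 1L
  hi <- i + 2L
  ylo <- ifelse(lo >= 1L & lo <= n, y[pmin(pmax(lo, 1L), n)], 0)
  yhi <- ifelse(hi >= 1L & hi <= n, y[pmin(pmax(hi, 1L), n)], 0)
  out <- ylo * (1 - f) + yhi * f
  out[p < 0 | p > n - 1L] <- 0
  out
}

# Trapezoidal quadrature weights for an increasing grid x.
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("trapezoidal quadrature needs at least two nodes")
  d <- diff(x)
  c(d[1L] / 2, (d[-1L] + d[-(n - 1L)]) / 2, d[n - 1L] / 2)
}

# Triangular (Bartlett) window with zero endpoints; w[k] = 1 - |2k/(n-1) - 1|.
bartlett_window <- function(n) {
  if (n < 1L) stop("window length must be positive")
  if (n == 1L) return(1)
  k <- 0:(n - 1)
  1 - abs(2 * k / (n - 1) - 1)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}
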