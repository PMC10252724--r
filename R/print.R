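# Print and plot methods.

#' @export
print.iq_dataset <- function(x, ...) {
  cat(sprintf("IQ dataset: %d fast-time x %d slow-time samples\n",
              x$acq$n_fast, x$acq$n_slow))
  cat(sprintf("  fc %.2f MHz, %d half cycles (%s), fs %.1f MHz\n",
              x$pulse$fc / 1e6, x$pulse$half_cycles, x$pulse$envelope,
              x$pulse$fs_fast / 1e6))
  cat(sprintf("  PRF %.0f Hz, theta %.1f deg, c %.0f m/s, SNR %s dB\n",
              x$acq$prf, x$acq$theta * 180 / pi, x$acq$c,
              format(x$acq$snr_db)))
  if (!is.null(x$truth)) cat(sprintf("  truth: %s waveform\n", x$truth$kind))
  invisible(x)
}

#' @export
print.velocity_spectrum <- function(x, ...) {
  ipk <- which.max(x$power)
  cat(sprintf("Velocity spectrum (%s): %d bins, peak %.3f m/s\n",
              x$meta$method, length(x$power), x$v[ipk]))
  cat(sprintf("  fc %.2f MHz, PRF %.0f Hz, %s segment(s)\n",
              x$meta$fc / 1e6, x$meta$prf, format(x$meta$n_segments)))
  invisible(x)
}

#' @export
print.sonogram <- function(x, ...) {
  cat(sprintf("Sonogram (%s): %d velocity bins x %d frames, %.2f s span\n",
              x$method, nrow(x$power), ncol(x$power),
              max(x$t) - min(x$t)))
  invisible(x)
}

#' @export
print.q_factor <- function(x, ...) {
  cat(sprintf("Q = %.3f (fc %.2f MHz, BW %.2f MHz)\n",
              x$q, x$fc / 1e6, x$bw / 1e6))
  invisible(x)
}

#' @export
print.wss_result <- function(x, ...) {
  cat(sprintf("WSS (%s): %.4f Pa (shear rate %.1f 1/s)%s\n",
              x$method, x$wss, x$shear_rate,
              if (is.na(x$position)) "" else paste0(" at ", x$position)))
  invisible(x)
}

#' Display a sonogram
#'
#' Image plot of log-compressed power over time and velocity.
#'
#' @param x A [build_sonogram()] result.
#' @param dynamic_range_db Display dynamic range in dB below the maximum.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sonogram <- function(x, dynamic_range_db = 40, ...) {
  p <- x$power / max(x$power)
  db <- 10 * log10(pmax(p, 10^(-dynamic_range_db / 10 - 1)))
  db <- pmax(db, -dynamic_range_db)
  graphics::image(x$t, x$v * 100, t(db), col = grDevices::grey.colors(64, 0, 1),
                  xlab = "time (s)", ylab = "velocity (cm/s)", ...)
  invisible(x)
}
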