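# Open IQ container: raw little-endian complex matrix (.iqz) plus a JSON
# metadata sidecar (.json), and plain-text (CSV) exports of results.

IQ_FORMAT_VERSION <- "1.0"

container_paths <- function(path) {
  base <- sub("\\.(iqz|json)$", "", path)
  list(bin = paste0(base, ".iqz"), json = paste0(base, ".json"))
}

#' Write an IQ dataset to the open container format
#'
#' Stores the complex matrix as raw little-endian complex128 values in
#' row-major order (fast-time rows, slow-time varying fastest) in
#' `<path>.iqz`, and all acquisition metadata plus the ground-truth
#' waveform parameters in a `<path>.json` sidecar.
#'
#' @param iq An `iq_dataset`.
#' @param path Output path; any `.iqz`/`.json` extension is stripped.
#' @return The two file paths, invisibly.
#' @export
write_iq_container <- function(iq, path) {
  if (!inherits(iq, "iq_dataset")) stop("'iq' must be an iq_dataset")
  p <- container_paths(path)
  meta <- list(
    format_version = IQ_FORMAT_VERSION,
    dtype = "complex128",
    n_fast = iq$acq$n_fast,
    n_slow = iq$acq$n_slow,
    fc_hz = iq$pulse$fc,
    fs_fast_hz = iq$pulse$fs_fast,
    prf_hz = iq$acq$prf,
    theta_rad = iq$acq$theta,
    c_ms = iq$acq$c,
    snr_db = if (is.finite(iq$acq$snr_db)) iq$acq$snr_db else NULL,
    seed = iq$acq$seed,
    half_cycles = iq$pulse$half_cycles,
    envelope = iq$pulse$envelope,
    truth_waveform = if (is.null(iq$truth)) NULL else
      c(list(kind = iq$truth$kind), iq$truth$params)
  )
  jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  con <- file(p$bin, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(iq$data)), con, endian = "little")
  invisible(unlist(p))
}

require_keys <- function(meta, keys) {
  for (k in keys) {
    if (is.null(meta[[k]])) stop(sprintf("metadata error: missing key '%s'", k))
  }
}

#' Read an IQ dataset from the open container format
#'
#' Validates the sidecar (format version, required keys) and the binary
#' payload size against the declared shape, then reconstructs a full
#' `iq_dataset` including the ground-truth waveform when present.
#'
#' @param path Container path (with or without extension).
#' @return An `iq_dataset`.
#' @export
read_iq_container <- function(path) {
  p <- container_paths(path)
  if (!file.exists(p$json)) stop(sprintf("missing sidecar: %s", p$json))
  if (!file.exists(p$bin)) stop(sprintf("missing matrix file: %s", p$bin))
  meta <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  if (is.null(meta$format_version)) stop("metadata error: missing key 'format_version'")
  if (!identical(meta$format_version, IQ_FORMAT_VERSION)) {
    stop(sprintf("unsupported container version '%s'", meta$format_version))
  }
  if (!identical(meta$dtype, "complex128")) {
    stop(sprintf("unsupported dtype '%s'", meta$dtype))
  }
  require_keys(meta, c("n_fast", "n_slow", "fc_hz", "fs_fast_hz", "prf_hz",
                       "theta_rad", "c_ms", "half_cycles", "envelope"))
  n_fast <- as.integer(meta$n_fast)
  n_slow <- as.integer(meta$n_slow)
  expect_bytes <- 16 * n_fast * n_slow
  got_bytes <- file.info(p$bin)$size
  if (got_bytes != expect_bytes) {
    stop(sprintf("shape mismatch: sidecar declares %d x %d (%d bytes) but matrix file has %d bytes",
                 n_fast, n_slow, expect_bytes, got_bytes))
  }
  con <- file(p$bin, "rb")
  on.exit(close(con))
  vec <- readBin(con, what = "complex", n = n_fast * n_slow, endian = "little")
  data <- t(matrix(vec, nrow = n_slow, ncol = n_fast))

  pulse <- pulse_spec(meta$fc_hz, meta$half_cycles, meta$envelope, meta$fs_fast_hz)
  acq <- acquisition_spec(prf = meta$prf_hz, n_slow = n_slow, n_fast = n_fast,
                          theta = meta$theta_rad, c = meta$c_ms,
                          snr_db = if (is.null(meta$snr_db)) Inf else meta$snr_db,
                          seed = meta$seed)
  truth <- NULL
  tw <- meta$truth_waveform
  if (!is.null(tw)) {
    args <- as.list(tw)
    kind <- args$kind
    args$kind <- NULL
    truth <- do.call(velocity_waveform, c(list(kind = kind), args))
  }
  structure(list(data = data, pulse = pulse, acq = acq, truth = truth),
            class = "iq_dataset")
}

#' Write a velocity spectrum as CSV
#'
#' Columns `f_d_hz`, `v_ms`, `power` (RFC 4180, header row included).
#'
#' @param vs A `velocity_spectrum`.
#' @param path Output CSV path.
#' @export
write_spectrum_csv <- function(vs, path) {
  utils::write.csv(
    data.frame(f_d_hz = vs$f_d, v_ms = vs$v, power = vs$power),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a sonogram as CSV
#'
#' First column is the velocity axis (`v_ms`); remaining columns hold one
#' frame each, named by frame centre time in milliseconds.
#'
#' @param sonogram A [build_sonogram()] result.
#' @param path Output CSV path.
#' @export
write_sonogram_csv <- function(sonogram, path) {
  m <- as.data.frame(sonogram$power)
  names(m) <- sprintf("t_%.3fms", sonogram$t * 1e3)
  utils::write.csv(cbind(data.frame(v_ms = sonogram$v), m), path,
                   row.names = FALSE)
  invisible(path)
}
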