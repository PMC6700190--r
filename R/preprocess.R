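#' Common average referencing
#'
#' Subtracts, at every sample, the mean voltage across channels from each
#' channel. This cancels noise shared across the array; the cross-channel
#' mean of the output is identically zero, and the operation is idempotent.
#'
#' @param rec a [voltage_recording()] with at least 2 channels.
#' @return A referenced [voltage_recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "voltage_recording"))
  if (ncol(rec$data) < 2)
    stop("common average referencing is undefined for a single channel")
  ref <- rowMeans(rec$data)
  rec$data <- rec$data - ref
  rec
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`) per
#' channel, so spike shapes used for templates are not phase-distorted.
#'
#' @param rec a [voltage_recording()].
#' @param low_hz,high_hz passband edges; must satisfy
#'   `0 < low_hz < high_hz < fs/2`. Defaults are the spike band 300--8000 Hz.
#' @param order filter order (per pass).
#' @return A filtered [voltage_recording()].
#' @export
bandpass_filter <- function(rec, low_hz = 300, high_hz = 8000, order = 4) {
  stopifnot(inherits(rec, "voltage_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("need 0 < low (%g) < high (%g) < Nyquist (%g)",
                 low_hz, high_hz, nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  n <- nrow(rec$data)
  # odd-reflection padding suppresses filtfilt edge transients
  p <- min(n - 1, round(3 * rec$fs / low_hz))
  for (c in seq_len(ncol(rec$data))) {
    x <- rec$data[, c]
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    rec$data[, c] <- signal::filtfilt(bf, xp)[(p + 1):(p + n)]
  }
  rec
}

#' Per-channel signal kurtosis
#'
#' Signal-to-noise score used for tetrode pad selection: the raw fourth
#' central moment `E[(v - E[v])^4]` of each channel over time. Note this is
#' neither normalized by the variance squared nor excess kurtosis, so it
#' scales with the fourth power of the signal amplitude; set
#' `normalized = TRUE` for the scale-free variant.
#'
#' @param rec a [voltage_recording()] with at least 2 samples.
#' @param normalized divide by the squared population variance.
#' @return Numeric vector, one score per channel (0 for constant channels).
#' @export
channel_kurtosis <- function(rec, normalized = FALSE) {
  stopifnot(inherits(rec, "voltage_recording"))
  if (nrow(rec$data) < 2) stop("need at least 2 samples")
  ctr <- sweep(rec$data, 2, colMeans(rec$data))
  m4 <- colMeans(ctr^4)
  if (normalized) {
    m2 <- colMeans(ctr^2)
    m4 <- ifelse(m4 == 0, 0, m4 / m2^2)
  }
  stats::setNames(m4, rec$channel_ids)
}

#' Select the best tetrode pads by kurtosis
#'
#' From a set of candidate pads within one depth range, picks the `n` with
#' the highest [channel_kurtosis()] (the pads with the best signal-to-noise
#' ratio). Deterministic; ties break toward the lower channel index.
#'
#' @param rec a [voltage_recording()].
#' @param candidate_pads integer channel indices (columns of `rec$data`).
#' @param n group size, 4 for a tetrode.
#' @return An object of class `tetrode_group` with sorted `channel_indices`
#'   and the per-candidate `scores`.
#' @export
select_tetrode <- function(rec, candidate_pads, n = 4) {
  stopifnot(inherits(rec, "voltage_recording"))
  candidate_pads <- as.integer(candidate_pads)
  if (anyDuplicated(candidate_pads)) stop("candidate pads must be distinct")
  if (any(candidate_pads < 1 | candidate_pads > ncol(rec$data)))
    stop("candidate pad index out of range")
  if (length(candidate_pads) < n)
    stop(sprintf("need at least %d candidate pads, got %d",
                 n, length(candidate_pads)))
  k <- channel_kurtosis(rec)[candidate_pads]
  ord <- order(-k, candidate_pads)
  sel <- sort(candidate_pads[ord[seq_len(n)]])
  structure(list(channel_indices = sel,
                 scores = stats::setNames(as.numeric(k), candidate_pads)),
            class = "tetrode_group")
}

#' @export
print.tetrode_group <- function(x, ...) {
  cat("<tetrode_group> channels:", paste(x$channel_indices, collapse = ", "),
      "\n")
  invisible(x)
}

#' Estimate the per-channel noise level
#'
#' Plain sample standard deviation of each channel over the full (filtered,
#' referenced) trace -- the noise floor the fixed voltage threshold is a
#' multiple of. A robust alternative (`mad`) is available but off by
#' default, matching the plain-SD convention of the detection threshold.
#'
#' @param rec a [voltage_recording()].
#' @param robust use the median absolute deviation (scaled to SD) instead.
#' @return An object of class `noise_model` with `sd_per_channel`.
#' @export
estimate_noise_sd <- function(rec, robust = FALSE) {
  stopifnot(inherits(rec, "voltage_recording"))
  est <- if (robust) {
    apply(rec$data, 2, stats::mad)
  } else {
    n <- nrow(rec$data)
    mu <- colMeans(rec$data)
    sqrt((colSums(rec$data^2) - n * mu^2) / (n - 1))
  }
  structure(list(sd_per_channel = stats::setNames(est, rec$channel_ids),
                 robust = robust),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model> sd (uV):",
      paste(sprintf("%.3g", x$sd_per_channel), collapse = ", "), "\n")
  invisible(x)
}
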