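#' First-round detection configuration
#'
#' Parameters of the standard fixed-voltage-threshold detector: the
#' threshold expressed as a multiple of the per-channel noise SD (the
#' conventional choice is 3, typically used in the 2.8--3.2 range), a
#' shadow (dead-time) period after every accepted event, and the clip
#' window extracted around each crossing. The clip spans `clip_pre_s`
#' before to `clip_post_s` after the crossing (k = 1.5 ms total by
#' default), giving `L = round(fs * k)` samples per channel.
#'
#' @param fs sampling frequency (Hz).
#' @param threshold_sd threshold multiplier in noise SDs.
#' @param shadow_s shadow period (s); 0.66 ms default.
#' @param clip_pre_s,clip_post_s clip window before/after the alignment
#'   point (s).
#' @return An object of class `detection_config` with derived fields
#'   `L` (clip length in samples), `pre_samples` and `shadow_samples`.
#' @examples
#' cfg <- detection_config() # fs 31250 -> L = 47, pre = 16 samples
#' @export
detection_config <- function(fs = 31250, threshold_sd = 3,
                             shadow_s = 0.00066,
                             clip_pre_s = 0.0005, clip_post_s = 0.001) {
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(threshold_sd, "threshold_sd")
  stop_if_not_scalar_pos(shadow_s, "shadow_s")
  stop_if_not_scalar_pos(clip_pre_s, "clip_pre_s")
  stop_if_not_scalar_pos(clip_post_s, "clip_post_s")
  k <- clip_pre_s + clip_post_s
  structure(list(fs = fs, threshold_sd = threshold_sd, shadow_s = shadow_s,
                 clip_pre_s = clip_pre_s, clip_post_s = clip_post_s,
                 k_s = k,
                 L = as.integer(round(fs * k)),
                 pre_samples = as.integer(round(fs * clip_pre_s)),
                 shadow_samples = fs * shadow_s),
            class = "detection_config")
}

#' Convert an `ntm_config` list into a `detection_config`
#' @param cfg a list from [load_config()].
#' @param threshold_sd optional override of the threshold multiplier.
#' @return A [detection_config()].
#' @export
as_detection_config <- function(cfg, threshold_sd = NULL) {
  if (inherits(cfg, "detection_config")) {
    if (!is.null(threshold_sd)) cfg$threshold_sd <- threshold_sd
    return(cfg)
  }
  detection_config(fs = cfg$fs,
                   threshold_sd = threshold_sd %||% cfg$threshold_sd,
                   shadow_s = cfg$shadow_ms / 1000,
                   clip_pre_s = cfg$clip_pre_ms / 1000,
                   clip_post_s = cfg$clip_post_ms / 1000)
}

#' Standard fixed-threshold spike detection
#'
#' Scans the (referenced, filtered) tetrode channels for negative-going
#' threshold crossings. A crossing is the first sample strictly below the
#' channel threshold `mean_c - threshold_sd * sd_c` after a sample
#' at-or-above it, on any channel of the group; all channels then share one
#' shadow clock, so no two accepted events are closer than `shadow_s`.
#'
#' @param rec a [voltage_recording()].
#' @param tetrode optional [select_tetrode()] result or integer channel
#'   indices; defaults to all channels.
#' @param noise optional [estimate_noise_sd()] result (computed if absent).
#' @param cfg a [detection_config()].
#' @return A [spike_events()] table (method `"standard"`, unit -1) whose
#'   times are the crossing times; 1-based crossing sample indices are in
#'   `attr(, "crossing_samples")`.
#' @export
detect_threshold_crossings <- function(rec, tetrode = NULL, noise = NULL,
                                       cfg = detection_config(fs = rec$fs)) {
  stopifnot(inherits(rec, "voltage_recording"))
  ch <- channel_indices(tetrode, rec)
  V <- select_channels(rec$data, ch)
  if (is.null(noise)) {
    sds <- estimate_noise_sd(rec)$sd_per_channel[ch]
  } else {
    sds <- noise$sd_per_channel[ch]
  }
  if (any(sds <= 0)) stop("zero noise SD on a channel; cannot set threshold")
  thr <- colMeans(V) - cfg$threshold_sd * sds
  idx <- cpp_detect_crossings(V, thr, cfg$shadow_samples)
  ev <- spike_events(time_s = (idx - 1) / rec$fs + rec$t0,
                     unit_id = -1L, method = "standard")
  attr(ev, "crossing_samples") <- idx
  attr(ev, "thresholds_uV") <- thr
  ev
}

channel_indices <- function(tetrode, rec) {
  if (is.null(tetrode)) return(seq_len(ncol(rec$data)))
  if (inherits(tetrode, "tetrode_group")) return(tetrode$channel_indices)
  as.integer(tetrode)
}

# Column subset without copying when all channels are requested in order.
select_channels <- function(V, ch) {
  if (length(ch) == ncol(V) && all(ch == seq_len(ncol(V)))) V
  else V[, ch, drop = FALSE]
}

#' Extract voltage clips around detected events
#'
#' Cuts an `L x N` window (from `clip_pre_s` before to `clip_post_s` after
#' the event sample, half-open in samples) around each event on every
#' channel of the group. Events whose window would run off the trace are
#' dropped, never zero-padded (padding would corrupt templates); the count
#' is reported in `attr(, "n_dropped")`.
#'
#' @param rec a [voltage_recording()].
#' @param events a [spike_events()] table (or numeric times in seconds).
#' @param cfg a [detection_config()].
#' @param tetrode channels as in [detect_threshold_crossings()].
#' @return An object of class `spike_clips`: waveform array `waves`
#'   (n x L x N), event `times` (s), sampling metadata.
#' @export
extract_clips <- function(rec, events,
                          cfg = detection_config(fs = rec$fs),
                          tetrode = NULL) {
  stopifnot(inherits(rec, "voltage_recording"))
  ch <- channel_indices(tetrode, rec)
  times <- if (is.data.frame(events)) events$time_s else as.numeric(events)
  centre <- round((times - rec$t0) * rec$fs) + 1
  starts <- centre - cfg$pre_samples
  keep <- starts >= 1 & (starts + cfg$L - 1) <= nrow(rec$data)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " event(s) too close to trace edges dropped")
  starts <- starts[keep]
  clips <- gather_clips(rec$data, starts, cfg$L, ch)
  structure(list(waves = clips,
                 times = (starts + cfg$pre_samples - 1) / rec$fs + rec$t0,
                 start_samples = starts,
                 fs = rec$fs, L = cfg$L, pre_samples = cfg$pre_samples,
                 channels = ch, aligned = FALSE),
            class = "spike_clips",
            n_dropped = n_dropped, kept = which(keep))
}

gather_clips <- function(V, starts, L, ch) {
  if (length(starts) == 0) return(array(0, dim = c(0, L, length(ch))))
  out <- cpp_gather_clips(V, as.integer(starts), as.integer(L),
                          as.integer(ch))
  array(out, dim = c(length(starts), L, length(ch)))
}

#' @export
print.spike_clips <- function(x, ...) {
  cat(sprintf("<spike_clips> %d clips, L = %d samples x %d channels%s\n",
              length(x$times), x$L, length(x$channels),
              if (isTRUE(x$aligned)) " (aligned)" else ""))
  invisible(x)
}

#' Align clips to their negative peak
#'
#' Re-centres every clip so the global (across-channel) negative peak sits
#' at the alignment index `round(fs * clip_pre_s)`, by re-extraction from
#' the source trace (not by padding). Clips whose peak is not interior to
#' the window, or whose required shift exceeds the pre-window, or whose
#' re-extraction would leave the trace, are dropped and counted. Two
#' crossings that align to the same trough are collapsed to one clip.
#'
#' @param clips a [extract_clips()] result.
#' @param rec the source [voltage_recording()].
#' @return A `spike_clips` object with `aligned = TRUE`; `times` hold the
#'   trough times in seconds.
#' @export
align_clips <- function(clips, rec) {
  stopifnot(inherits(clips, "spike_clips"), inherits(rec, "voltage_recording"))
  n <- length(clips$times)
  L <- clips$L
  N <- length(clips$channels)
  if (n == 0) {
    clips$aligned <- TRUE
    return(clips)
  }
  flat <- matrix(clips$waves, n, L * N)
  jflat <- max.col(-flat, ties.method = "first")
  j <- (jflat - 1L) %% L + 1L            # within-window index of the trough
  align_idx <- clips$pre_samples + 1L
  shift <- j - align_idx
  ok <- j > 1L & j < L & abs(shift) <= clips$pre_samples
  new_starts <- clips$start_samples + shift
  ok <- ok & new_starts >= 1 & (new_starts + L - 1) <= nrow(rec$data)
  new_starts <- new_starts[ok]
  dup <- duplicated(new_starts)
  new_starts <- new_starts[!dup]
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " clip(s) without an alignable interior trough dropped")
  structure(list(waves = gather_clips(rec$data, new_starts, L, clips$channels),
                 times = (new_starts + clips$pre_samples - 1) / rec$fs + rec$t0,
                 start_samples = new_starts,
                 fs = clips$fs, L = L, pre_samples = clips$pre_samples,
                 channels = clips$channels, aligned = TRUE),
            class = "spike_clips",
            n_dropped = n_dropped, n_duplicates = sum(dup))
}
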