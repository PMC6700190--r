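#' Construct a multichannel voltage recording
#'
#' The raw substrate of all detection: a samples-by-channels matrix of
#' extracellular voltage in microvolts plus its sampling rate.
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs sampling frequency in Hz (31250 Hz for the recordings this
#'   pipeline was designed around).
#' @param channel_ids optional channel labels; defaults to `1:ncol(data)`.
#' @param t0 start time of the first sample, in seconds.
#' @return An object of class `voltage_recording` with elements `data`,
#'   `fs`, `channel_ids`, `t0`.
#' @examples
#' rec <- voltage_recording(matrix(rnorm(400), 100, 4), fs = 31250)
#' n_samples(rec)
#' @export
voltage_recording <- function(data, fs, channel_ids = NULL, t0 = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stop_if_not_scalar_pos(fs, "fs")
  if (!all(is.finite(data))) stop("voltage data must be finite (no NA/NaN/Inf)")
  channel_ids <- channel_ids %||% seq_len(ncol(data))
  if (length(channel_ids) != ncol(data))
    stop("channel_ids length must equal the number of channels")
  structure(list(data = data, fs = fs, channel_ids = channel_ids, t0 = t0),
            class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("<voltage_recording> %d samples x %d channels @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' Number of samples / channels in a recording
#' @param rec a [voltage_recording()].
#' @return integer count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' @rdname n_samples
#' @export
n_channels <- function(rec) ncol(rec$data)

#' Write / read a voltage recording as flat binary plus JSON sidecar
#'
#' The container is a flat little-endian float64 binary file (column-major:
#' all samples of channel 1, then channel 2, ...) with a JSON sidecar
#' `<path>.json` holding `dtype`, `n_channels`, `n_samples`, `fs`, `units`,
#' `t0` and `channel_ids`.
#'
#' @param rec a [voltage_recording()].
#' @param path file path for the binary payload.
#' @return `write_voltage` returns `path` invisibly; `read_voltage` returns a
#'   [voltage_recording()].
#' @export
write_voltage <- function(rec, path) {
  stopifnot(inherits(rec, "voltage_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  meta <- list(dtype = "float64", n_channels = ncol(rec$data),
               n_samples = nrow(rec$data), fs = rec$fs, units = "uV",
               t0 = rec$t0, channel_ids = rec$channel_ids, order = "column")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_voltage
#' @param format container format; only `"flat"` (flat binary + JSON sidecar)
#'   is supported by this build.
#' @export
read_voltage <- function(path, format = c("flat", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 voltage containers are not supported by this build; ",
         "use the flat-binary + JSON-sidecar format")
  if (!file.exists(path)) stop("voltage file not found: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("metadata missing: sidecar file not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (key in c("dtype", "n_channels", "fs")) {
    if (is.null(meta[[key]]))
      stop("metadata missing: sidecar lacks required key '", key, "'")
  }
  if (!identical(meta$dtype, "float64"))
    stop("unsupported dtype: ", meta$dtype)
  n_total <- file.size(path) / 8
  if (n_total == 0) stop("empty voltage file: ", path)
  if (n_total %% meta$n_channels != 0)
    stop("file size inconsistent with n_channels")
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n_total, size = 8, endian = "little")
  if (anyNA(x) || any(is.nan(x))) stop("NaN values in voltage data")
  voltage_recording(matrix(x, ncol = meta$n_channels),
                    fs = meta$fs,
                    channel_ids = meta$channel_ids %||% NULL,
                    t0 = meta$t0 %||% 0)
}

#' Construct a spike event table
#'
#' Detected (or ground-truth) spike times with unit labels and detection
#' provenance. Times are in seconds at the alignment point (the negative
#' waveform peak), the convention shared by first-round, template-matching
#' and ground-truth tables so they are directly comparable.
#'
#' @param time_s spike times in seconds.
#' @param unit_id integer labels; -1 denotes multi-unit / unassigned.
#' @param method one of `"standard"`, `"ntm"`, `"tm"`, `"truth"`.
#' @param trial_id optional trial indices.
#' @param ... further columns (e.g. a similarity value) carried through.
#' @return A `data.frame` of class `spike_events`, sorted by time.
#' @export
spike_events <- function(time_s = numeric(), unit_id = -1L,
                         method = "standard", trial_id = NA_integer_, ...) {
  n <- length(time_s)
  df <- data.frame(time_s = as.numeric(time_s),
                   unit_id = as.integer(rep_len(unit_id, n)),
                   method = rep_len(as.character(method), n),
                   trial_id = rep_len(as.integer(trial_id), n),
                   ...)
  if (n && any(df$unit_id < -1L)) stop("unit_id must be >= -1")
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_events", "data.frame")
  df
}

#' Write / read spike event tables as CSV
#'
#' The CSV holds the four canonical columns `time_s, unit_id, method,
#' trial_id`; `read_events(write_events(x))` reproduces `x` up to
#' floating-point text representation.
#'
#' @param events a [spike_events()] table.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)[, c("time_s", "unit_id", "method", "trial_id")]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "unit_id", "method", "trial_id")
  if (!all(need %in% names(df)))
    stop("event CSV must have columns: ", paste(need, collapse = ", "))
  spike_events(df$time_s, df$unit_id, df$method, df$trial_id)
}

#' Construct a stimulus schedule
#'
#' @param trial_start_s stimulus onset times in seconds, strictly increasing.
#' @param stimulus_id integer stimulus codes; 0..8 index the nine whiskers,
#'   9 codes sham (no-stimulus) trials.
#' @return A `data.frame` of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(trial_start_s, stimulus_id) {
  if (length(trial_start_s) != length(stimulus_id))
    stop("trial_start_s and stimulus_id lengths differ")
  if (length(trial_start_s) > 1 && any(diff(trial_start_s) <= 0))
    stop("trial starts must be strictly increasing")
  df <- data.frame(trial_start_s = as.numeric(trial_start_s),
                   stimulus_id = as.integer(stimulus_id))
  class(df) <- c("stimulus_schedule", "data.frame")
  df
}

#' @rdname stimulus_schedule
#' @param schedule a `stimulus_schedule`.
#' @param path CSV path.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname stimulus_schedule
#' @export
read_schedule <- function(path) {
  df <- read.csv(path)
  stimulus_schedule(df$trial_start_s, df$stimulus_id)
}

ntm_defaults <- function() {
  list(fs = 31250, threshold_sd = 3.0, shadow_ms = 0.66,
       clip_pre_ms = 0.5, clip_post_ms = 1.0, bandpass = c(300, 8000),
       reject_sim = 0.7, merge_ms = 0.5, match_tol_ms = 0.2,
       refractory_violation_ms = 1.5, shadow_scope = "tetrode")
}

#' Load a pipeline configuration
#'
#' Reads a YAML or JSON file and merges it over the documented defaults
#' (`threshold_sd = 3`, `shadow_ms = 0.66`, `clip_pre_ms = 0.5`,
#' `clip_post_ms = 1`, `bandpass = c(300, 8000)` Hz, `fs = 31250` Hz).
#' Unknown keys warn; a value whose type does not match the default errors.
#'
#' @param path optional path to a `.yaml`/`.yml` or `.json` file; `NULL`
#'   returns pure defaults.
#' @param overrides named list applied after the file.
#' @return A named list of class `ntm_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- ntm_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
      yaml = , yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop("unsupported config format: .", ext, " (use YAML or JSON)"))
    user <- user %||% list()
  }
  user <- utils::modifyList(user, overrides)
  for (key in names(user)) {
    if (!key %in% names(cfg)) {
      warning("unknown config key ignored: ", key)
      next
    }
    val <- user[[key]]
    if (is.numeric(cfg[[key]]) && !is.numeric(val))
      stop(sprintf("config key '%s' must be numeric, got %s",
                   key, class(val)[1]))
    if (is.character(cfg[[key]]) && !is.character(val))
      stop(sprintf("config key '%s' must be character, got %s",
                   key, class(val)[1]))
    cfg[[key]] <- val
  }
  structure(cfg, class = "ntm_config")
}
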