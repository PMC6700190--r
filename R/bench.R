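#' Drop near-simultaneous cross-unit truth spikes
#'
#' Removes every single-unit spike participating in a pair of spikes from
#' two different single units within `window_s` of each other, to avoid
#' ambiguity when attributing detections to units. Multi-unit rows are
#' untouched. Within-unit pairs cannot occur at this window because of the
#' refractory period.
#'
#' @param truth a ground-truth [spike_events()] table.
#' @param window_s ambiguity window (s).
#' @return The filtered table; `attr(, "dropped_fraction")` holds the
#'   dropped fraction of single-unit spikes.
#' @export
drop_near_simultaneous <- function(truth, window_s = 5e-4) {
  su <- which(truth$unit_id >= 0)
  drop <- logical(length(su))
  if (length(su) > 1) {
    t_su <- truth$time_s[su]
    u_su <- truth$unit_id[su]
    dt <- diff(t_su)
    bad <- which(dt <= window_s & u_su[-1] != u_su[-length(u_su)])
    drop[bad] <- TRUE
    drop[bad + 1] <- TRUE
  }
  out <- truth[-su[drop], , drop = FALSE]
  if (length(su) == 0 || !any(drop)) out <- truth
  class(out) <- class(truth)
  attr(out, "dropped_fraction") <- if (length(su)) mean(drop) else 0
  attr(out, "n_dropped") <- sum(drop)
  out
}

# Greedy one-to-one matching of two sorted time vectors by increasing
# absolute time difference within +-tol. Returns index vectors into the
# candidate pair list plus assignment maps.
match_times_greedy <- function(from, to, tol_s) {
  nf <- length(from)
  nt <- length(to)
  if (nf == 0 || nt == 0) {
    return(list(from_assigned = rep(NA_integer_, nf),
                to_assigned = rep(NA_integer_, nt)))
  }
  of <- order(from); ot <- order(to)
  fs <- from[of]; ts <- to[ot]
  lo <- findInterval(fs - tol_s, ts, left.open = TRUE) + 1L
  hi <- findInterval(fs + tol_s, ts)
  n_cand <- pmax(hi - lo + 1L, 0L)
  fi <- rep.int(seq_len(nf), n_cand)
  ti <- unlist(lapply(which(n_cand > 0), function(i) lo[i]:hi[i]),
               use.names = FALSE)
  if (length(fi) == 0) {
    return(list(from_assigned = rep(NA_integer_, nf),
                to_assigned = rep(NA_integer_, nt)))
  }
  dt <- abs(fs[fi] - ts[ti])
  ord <- order(dt)
  f_taken <- logical(nf)
  t_taken <- logical(nt)
  from_assigned <- rep(NA_integer_, nf)
  to_assigned <- rep(NA_integer_, nt)
  for (k in ord) {
    i <- fi[k]; j <- ti[k]
    if (!f_taken[i] && !t_taken[j]) {
      f_taken[i] <- TRUE
      t_taken[j] <- TRUE
      from_assigned[of[i]] <- ot[j]
      to_assigned[ot[j]] <- of[i]
    }
  }
  list(from_assigned = from_assigned, to_assigned = to_assigned)
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching by increasing time difference within
#' `+-tol_s`. A matched detection is attributed to the truth spike's unit;
#' an unmatched truth spike is a miss, an unmatched detection a false
#' alarm. Multi-unit truth rows take part in the matching (so background
#' spikes absorb their own detections) but only single units are scored.
#'
#' @param detections a [spike_events()] table.
#' @param truth a (typically [drop_near_simultaneous()]-filtered)
#'   ground-truth table.
#' @param tol_s matching tolerance (s).
#' @return An object of class `match_result`: `per_unit` data frame
#'   (`unit_id`, `n_truth`, `tp`, `miss`, `detection_fraction`),
#'   `n_false_alarms`, `mean_detection_fraction`, and the truth-row match
#'   map `truth_matched_by` (detection row or NA).
#' @export
match_detections_to_truth <- function(detections, truth, tol_s = 2e-4) {
  m <- match_times_greedy(detections$time_s, truth$time_s, tol_s)
  matched_truth <- !is.na(m$to_assigned)
  units <- sort(unique(truth$unit_id[truth$unit_id >= 0]))
  per_unit <- do.call(rbind, lapply(units, function(u) {
    rows <- truth$unit_id == u
    tp <- sum(matched_truth & rows)
    data.frame(unit_id = u, n_truth = sum(rows), tp = tp,
               miss = sum(rows) - tp,
               detection_fraction = if (sum(rows)) tp / sum(rows) else NA_real_)
  }))
  structure(list(per_unit = per_unit,
                 n_false_alarms = sum(is.na(m$from_assigned)),
                 mean_detection_fraction = mean(per_unit$detection_fraction),
                 truth_matched_by = m$to_assigned),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> mean detection fraction %.3f, %d false alarms\n",
              x$mean_detection_fraction, x$n_false_alarms))
  print.data.frame(x$per_unit, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Classify why the standard method missed each spike
#'
#' A miss is `"shadowed"` if an accepted first-round event fell within the
#' shadow period before the miss's own threshold crossing; otherwise
#' `"sub_threshold"` if the spike's clip window never crosses the voltage
#' threshold; anything else is `"other"`.
#'
#' @param missed_times trough times (s) of missed truth spikes.
#' @param rec the [voltage_recording()] detection ran on.
#' @param events the standard-method [detect_threshold_crossings()] output
#'   (carries crossing samples and thresholds).
#' @param cfg the [detection_config()] used.
#' @param tetrode channels as in [detect_threshold_crossings()].
#' @return Factor with levels `shadowed`, `sub_threshold`, `other`.
#' @export
classify_miss_cause <- function(missed_times, rec, events,
                                cfg = detection_config(fs = rec$fs),
                                tetrode = NULL) {
  lv <- c("shadowed", "sub_threshold", "other")
  if (length(missed_times) == 0)
    return(factor(character(0), levels = lv))
  ch <- channel_indices(tetrode, rec)
  V <- rec$data[, ch, drop = FALSE]
  thr <- attr(events, "thresholds_uV")
  cross <- attr(events, "crossing_samples")
  below_any <- function(t) any(V[t, ] < thr)
  out <- character(length(missed_times))
  for (i in seq_along(missed_times)) {
    c0 <- round((missed_times[i] - rec$t0) * rec$fs) + 1
    c0 <- min(max(c0, 1), nrow(V))
    if (!below_any(c0)) {
      # the spike's own trough never reaches the threshold
      out[i] <- "sub_threshold"
      next
    }
    # the spike's own crossing: start of the contiguous sub-threshold run
    # containing its trough (bounded by the clip pre-window)
    own <- c0
    while (own > 1 && c0 - own < cfg$pre_samples && below_any(own - 1))
      own <- own - 1
    prior <- cross[cross < own & own - cross <= cfg$shadow_samples]
    out[i] <- if (length(prior)) "shadowed" else "other"
  }
  factor(out, levels = lv)
}

#' Benchmark detection methods across first-round thresholds
#'
#' For each threshold multiplier in `grid`: run standard fixed-threshold
#' detection; align clips and label them against the (unfiltered) truth
#' table (ground-truth labels stand in for clustering, which is not needed
#' to evaluate detection); build per-unit templates; fit ROC thresholds on
#' per-clip cosines (NTM) and dot products (TM); run both sliding
#' detectors; and score all three methods against the
#' near-simultaneous-filtered truth. A threshold that yields no clips for
#' any unit is recorded as `NA` (undefined), not zero.
#'
#' @param dataset a [make_benchmark_scenario()] / [render_voltage()]
#'   result.
#' @param grid threshold multipliers (noise SDs).
#' @param tol_s truth-matching tolerance (s).
#' @param merge_s cross-template merge window (s).
#' @param min_clips minimum labeled clips to build a unit's template.
#' @param verbose print one line per threshold.
#' @return An object of class `sweep_result`: a data frame with columns
#'   `threshold_sd`, `method`, `mean_fraction`, `sd_across_units`;
#'   per-unit fractions in `attr(, "per_unit")`.
#' @export
threshold_sweep <- function(dataset, grid = seq(2, 6, by = 0.5),
                            tol_s = 2e-4, merge_s = 5e-4, min_clips = 2,
                            verbose = FALSE) {
  stopifnot(inherits(dataset, "surrogate_dataset"))
  rec <- dataset$voltage
  truth_f <- drop_near_simultaneous(dataset$truth)
  units <- sort(unique(dataset$truth$unit_id[dataset$truth$unit_id >= 0]))
  noise <- estimate_noise_sd(rec)
  cfg0 <- detection_config(fs = rec$fs)
  q <- cpp_rolling_sumsq(rec$data, cfg0$L)
  methods <- c("standard", "tm", "ntm")
  per_unit <- array(NA_real_, dim = c(length(grid), 3, length(units)),
                    dimnames = list(NULL, methods, units))
  rows <- list()
  for (g in seq_along(grid)) {
    cfg <- detection_config(fs = rec$fs, threshold_sd = grid[g])
    ev <- detect_threshold_crossings(rec, NULL, noise, cfg)
    # negative-peak alignment without materializing every clip: only the
    # labeled (single-unit) clips are gathered, for template building; all
    # per-clip similarities are read off the sliding traces at the clip
    # start offsets, since a clip is exactly the window starting there
    troughs <- cpp_align_events(rec$data, attr(ev, "crossing_samples"),
                                cfg$pre_samples, cfg$L)
    troughs <- unique(troughs[!is.na(troughs)])
    starts <- troughs - cfg$pre_samples
    ok <- starts >= 1 & starts <= length(q)
    starts <- starts[ok]
    if (length(starts) == 0) {
      rows[[g]] <- data.frame(threshold_sd = grid[g], method = methods,
                              mean_fraction = NA_real_,
                              sd_across_units = NA_real_)
      next
    }
    times <- (starts + cfg$pre_samples - 1) / rec$fs + rec$t0
    m <- match_times_greedy(times, dataset$truth$time_s, tol_s)
    labels <- rep(-1L, length(times))
    hit <- which(!is.na(m$from_assigned))
    labels[hit] <- dataset$truth$unit_id[m$from_assigned[hit]]
    std <- match_detections_to_truth(
      spike_events(times, -1L, "standard"), truth_f, tol_s)
    per_unit[g, "standard", ] <- std$per_unit$detection_fraction

    lab_units <- sort(unique(labels[labels >= 0]))
    lab_units <- lab_units[vapply(lab_units,
                                  function(u) sum(labels == u),
                                  0L) >= min_clips]
    if (length(lab_units) > 0) {
      sel <- labels >= 0
      unit_clips <- structure(
        list(waves = gather_clips(rec$data, starts[sel], cfg$L,
                                  seq_len(ncol(rec$data))),
             times = times[sel], start_samples = starts[sel],
             fs = rec$fs, L = cfg$L, pre_samples = cfg$pre_samples,
             channels = seq_len(ncol(rec$data)), aligned = TRUE),
        class = "spike_clips")
      tm_list <- list()
      ntm_list <- list()
      for (u in lab_units) {
        tp <- compute_template(unit_clips, labels[sel], u)
        key <- as.character(u)
        mu_norm <- sqrt(sum(tp$mu^2))
        C <- cpp_sliding_dot(rec$data, tp$mu_mat)
        S <- C / (sqrt(q) * mu_norm)
        S[q == 0] <- 0
        a_ntm <- roc_alpha_for_unit(S[starts], labels, u)
        a_tm <- roc_alpha_for_unit(C[starts], labels, u)
        i_ntm <- cpp_epoch_peaks(S, a_ntm$alpha, cfg$shadow_samples)
        i_tm <- cpp_epoch_peaks(C, a_tm$alpha, cfg$shadow_samples)
        ntm_list[[key]] <- spike_events(
          (i_ntm - 1 + cfg$pre_samples) / rec$fs, u, "ntm",
          sim = S[i_ntm])
        tm_list[[key]] <- spike_events(
          (i_tm - 1 + cfg$pre_samples) / rec$fs, u, "tm",
          sim = S[i_tm])   # arbitration always compares cosines
      }
      ntm_ev <- merge_template_events(ntm_list, merge_s)
      tm_ev <- merge_template_events(tm_list, merge_s)
      per_unit[g, "ntm", ] <-
        match_detections_to_truth(ntm_ev, truth_f, tol_s)$per_unit$detection_fraction
      per_unit[g, "tm", ] <-
        match_detections_to_truth(tm_ev, truth_f, tol_s)$per_unit$detection_fraction
    }
    rows[[g]] <- data.frame(
      threshold_sd = grid[g], method = methods,
      mean_fraction = apply(per_unit[g, , , drop = FALSE], 2, mean),
      sd_across_units = apply(per_unit[g, , , drop = FALSE], 2, stats::sd))
    if (verbose)
      message(sprintf("threshold %.1f SD: std %.3f | tm %.3f | ntm %.3f",
                      grid[g], rows[[g]]$mean_fraction[1],
                      rows[[g]]$mean_fraction[2], rows[[g]]$mean_fraction[3]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, per_unit = per_unit,
            dropped_fraction = attr(truth_f, "dropped_fraction"),
            class = c("sweep_result", "data.frame"))
}

#' @export
plot.sweep_result <- function(x, ...) {
  df <- as.data.frame(x)
  methods <- c("standard", "tm", "ntm")
  cols <- c(standard = "grey40", tm = "steelblue", ntm = "firebrick")
  thr <- sort(unique(df$threshold_sd))
  plot(range(thr), c(0, 1), type = "n",
       xlab = "first-round threshold (noise SD)",
       ylab = "mean detection fraction", ...)
  for (m in methods) {
    d <- df[df$method == m, ]
    lines(d$threshold_sd, d$mean_fraction, type = "b", col = cols[m], pch = 16)
  }
  legend("bottomleft", legend = toupper(methods), col = cols, lty = 1,
         pch = 16, bty = "n")
  invisible(x)
}

# Assign events to trials; returns trial index (NA outside every window)
# and time relative to stimulus onset.
events_to_trials <- function(times, schedule, window_s) {
  starts <- schedule$trial_start_s
  idx <- findInterval(times, starts + window_s[1])
  rel <- times - starts[pmax(idx, 1)]
  ok <- idx >= 1 & rel >= window_s[1] & rel < window_s[2]
  idx[!ok] <- NA_integer_
  list(trial = idx, rel = rel)
}

#' Peri-stimulus time histogram
#'
#' Spike counts per time bin, averaged over the trials of each stimulus
#' and converted to a rate in Hz.
#'
#' @param events a [spike_events()] table (filter to one unit first for a
#'   per-unit PSTH).
#' @param schedule a [stimulus_schedule()] (times are stimulus onsets).
#' @param bin_ms bin width (ms).
#' @param window_s time window around onset.
#' @return Matrix of rates (Hz), stimuli x bins, with attributes
#'   `bin_centers_s` and `stimuli`.
#' @export
psth <- function(events, schedule, bin_ms = 10, window_s = c(-0.2, 0.4)) {
  breaks <- seq(window_s[1], window_s[2], by = bin_ms / 1000)
  stimuli <- sort(unique(schedule$stimulus_id))
  at <- events_to_trials(events$time_s, schedule, window_s)
  out <- matrix(0, length(stimuli), length(breaks) - 1,
                dimnames = list(stimuli, NULL))
  for (k in seq_along(stimuli)) {
    trials <- which(schedule$stimulus_id == stimuli[k])
    sel <- !is.na(at$trial) & at$trial %in% trials
    counts <- if (any(sel))
      table(cut(at$rel[sel], breaks, right = FALSE)) else rep(0, ncol(out))
    out[k, ] <- as.numeric(counts) / length(trials) / (bin_ms / 1000)
  }
  attr(out, "bin_centers_s") <- breaks[-1] - bin_ms / 2000
  attr(out, "stimuli") <- stimuli
  out
}

#' Stimulus-evoked and spontaneous firing rates
#'
#' Mean spikes per trial inside the post-onset window, divided by the
#' window length, for each whisker stimulus; sham trials (stimulus 9)
#' provide the spontaneous rate.
#'
#' @inheritParams psth
#' @param window_s evoked counting window after stimulus onset (s).
#' @param sham_id stimulus code of sham trials.
#' @return List with `evoked` (named rate vector, Hz, one per non-sham
#'   stimulus) and `spontaneous` (Hz; `NA` with a warning when the
#'   schedule has no sham trials).
#' @export
evoked_rate <- function(events, schedule, window_s = c(0, 0.125),
                        sham_id = 9L) {
  at <- events_to_trials(events$time_s, schedule, window_s)
  width <- diff(window_s)
  stimuli <- sort(unique(schedule$stimulus_id))
  rate_of <- function(sid) {
    trials <- which(schedule$stimulus_id == sid)
    sum(!is.na(at$trial) & at$trial %in% trials) / length(trials) / width
  }
  ev_ids <- setdiff(stimuli, sham_id)
  evoked <- vapply(ev_ids, rate_of, 0)
  names(evoked) <- ev_ids
  spont <- if (sham_id %in% stimuli) rate_of(sham_id) else {
    warning("no sham trials in schedule; spontaneous rate undefined")
    NA_real_
  }
  list(evoked = evoked, spontaneous = spont)
}

#' Percent gain in detected rate
#'
#' `100 * (rate_ntm - rate_standard) / rate_standard`; undefined (NA) where
#' the standard rate is zero, so such entries drop out of averages.
#'
#' @param rate_ntm,rate_standard rates (Hz), vectorized.
#' @return Percent gains.
#' @export
percent_gain <- function(rate_ntm, rate_standard) {
  ifelse(is.na(rate_standard) | rate_standard == 0, NA_real_,
         100 * (rate_ntm - rate_standard) / rate_standard)
}

#' Rank-ordered receptive field
#'
#' Sorts each unit's per-stimulus rates from strongest to weakest, then
#' averages across units at each rank.
#'
#' @param per_stimulus_rates numeric vector (one unit) or matrix
#'   (units x stimuli).
#' @return Mean rate per rank (descending); the per-unit sorted matrix is
#'   attached as `attr(, "per_unit")` for matrix input.
#' @export
ranked_receptive_field <- function(per_stimulus_rates) {
  if (is.null(dim(per_stimulus_rates)))
    return(sort(per_stimulus_rates, decreasing = TRUE))
  sorted <- t(apply(per_stimulus_rates, 1, sort, decreasing = TRUE))
  structure(colMeans(sorted), per_unit = sorted)
}

#' Waveform shape features of a template
#'
#' On the template's dominant channel (largest negative peak): the
#' negative amplitude (current sink), the positive peak after the trough
#' (current source), and the spike width (trough-to-peak time). The width
#' is undefined (NA) when no positive deflection follows the trough.
#'
#' @param template a [compute_template()] result, an `L x N` matrix, or a
#'   single-channel numeric vector.
#' @param fs sampling rate (Hz); taken from a `spike_template` input.
#' @return Named vector `neg_amplitude_uV`, `pos_peak_uV`,
#'   `spike_width_ms`.
#' @export
waveform_features <- function(template, fs = NULL) {
  if (inherits(template, "spike_template")) {
    fs <- fs %||% template$fs
    m <- template$mu_mat
  } else {
    m <- as.matrix(template)
  }
  if (is.null(fs)) stop("fs required for width in ms")
  dom <- which.min(apply(m, 2, min))
  w <- m[, dom]
  i0 <- which.min(w)
  neg <- w[i0]
  if (i0 == length(w)) {
    pos <- NA_real_; width <- NA_real_
  } else {
    after <- w[(i0 + 1):length(w)]
    pos <- max(after)
    if (pos <= 0) {
      pos <- NA_real_; width <- NA_real_
    } else {
      width <- which.max(after) / fs * 1000
    }
  }
  c(neg_amplitude_uV = neg, pos_peak_uV = pos, spike_width_ms = width)
}
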