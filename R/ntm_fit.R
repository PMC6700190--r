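#' Fit a normalized-template-matching spike detector
#'
#' The model-fitting entry point of the package. A first round of standard
#' fixed-threshold detection extracts and aligns waveform clips; clips are
#' labeled (by a supplied label vector from any clusterer, or by matching
#' to a ground-truth table on simulated data); per-unit mean-waveform
#' templates are built and gated by the single-unit quality criteria; and
#' a per-unit similarity threshold `alpha_i` is fitted by the ROC rule
#' maximizing `(TP + CR)/2`. The fitted object detects spikes on new (or
#' the same) voltage data via [predict.ntm()].
#'
#' @param rec a [voltage_recording()] (referenced and band-pass filtered;
#'   see [common_average_reference()] and [bandpass_filter()]).
#' @param labels integer unit labels for the aligned first-round clips
#'   (-1 = unassigned), or `NULL` to label from `truth`.
#' @param truth optional ground-truth [spike_events()] table used to label
#'   clips when `labels` is `NULL` (simulation workflows).
#' @param tetrode channels as in [detect_threshold_crossings()].
#' @param config a [detection_config()] or [load_config()] list.
#' @param kind detection statistic, `"ntm"` (sliding cosine) or `"tm"`
#'   (sliding dot product).
#' @param min_spikes minimum clips per unit for a template.
#' @param quality_gate drop templates failing the single-unit criteria
#'   (<0.5% refractory violations, <30% estimated missing spikes).
#' @param label_tol_s matching tolerance when labeling from `truth`.
#' @return An object of class `ntm` with components `templates`, `alphas`,
#'   `quality`, `first_round` (events, clips summary, labels), `config`,
#'   `noise`, `channels`, `kind`, `call`.
#' @seealso [predict.ntm()], [run_second_round()], [threshold_sweep()]
#' @examples
#' \donttest{
#' ds <- make_benchmark_scenario("baseline", seed = 1, n_trials_per_stim = 2)
#' fit <- ntm_fit(ds$voltage, truth = ds$truth)
#' fit
#' ev <- predict(fit)
#' }
#' @export
ntm_fit <- function(rec, labels = NULL, truth = NULL, tetrode = NULL,
                    config = detection_config(fs = rec$fs),
                    kind = c("ntm", "tm"), min_spikes = 10,
                    quality_gate = TRUE, label_tol_s = 2e-4) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "voltage_recording"))
  cfg <- as_detection_config(config)
  ch <- channel_indices(tetrode, rec)
  noise <- estimate_noise_sd(
    voltage_recording(rec$data[, ch, drop = FALSE], rec$fs, t0 = rec$t0))
  names(noise$sd_per_channel) <- ch
  events <- detect_threshold_crossings(rec, ch, NULL, cfg)
  clips <- align_clips(extract_clips(rec, events, cfg, ch), rec)
  if (is.null(labels)) {
    if (is.null(truth))
      stop("either clip 'labels' (from a clusterer) or a 'truth' table is required")
    labels <- label_clips_from_truth(clips, truth, tol_s = label_tol_s)
  }
  if (length(labels) != length(clips$times))
    stop("need one label per aligned clip (", length(clips$times), ")")
  templates <- compute_templates(clips, labels, min_spikes = min_spikes)
  thr_uV <- attr(events, "thresholds_uV")
  quality <- lapply(templates, function(tp) {
    sel <- labels == tp$unit_id
    amps <- apply(clips$waves[sel, , , drop = FALSE], 1, min)
    dom <- which.min(apply(tp$mu_mat, 2, min))
    quality_report(clips$times[sel], amps, thr_uV[dom])
  })
  if (quality_gate && length(templates)) {
    pass <- vapply(quality, function(q) isTRUE(q$passes_single_unit), TRUE)
    if (!any(pass)) warning("no template passes the single-unit quality gate")
    templates <- templates[pass]
  }
  n <- length(clips$times)
  flat <- matrix(clips$waves, n, clips$L * length(ch))
  alphas <- lapply(templates, function(tp) {
    sims <- if (kind == "ntm") clip_similarity_matrix(flat, list(tp))[, 1]
            else as.vector(flat %*% tp$mu)
    roc_alpha_for_unit(sims, labels, tp$unit_id)
  })
  structure(list(templates = templates, alphas = alphas, quality = quality,
                 first_round = list(events = events, n_clips = n,
                                    labels = labels, clips = clips),
                 config = cfg, noise = noise, channels = ch, kind = kind,
                 rec = rec, call = match.call()),
            class = "ntm")
}

# Label aligned clips by greedy nearest-time matching against a truth table.
label_clips_from_truth <- function(clips, truth, tol_s = 2e-4) {
  m <- match_times_greedy(clips$times, truth$time_s, tol_s)
  labels <- rep(-1L, length(clips$times))
  hit <- which(!is.na(m$from_assigned))
  labels[hit] <- truth$unit_id[m$from_assigned[hit]]
  labels
}

#' @export
print.ntm <- function(x, ...) {
  cat(sprintf("Normalized template matching fit (%s)\n", toupper(x$kind)))
  cat(sprintf("  first round: threshold %.2f SD, shadow %.2f ms, %d clips\n",
              x$config$threshold_sd, 1000 * x$config$shadow_s,
              x$first_round$n_clips))
  cat(sprintf("  %d template(s):\n", length(x$templates)))
  for (key in names(x$templates)) {
    a <- x$alphas[[key]]
    cat(sprintf("    unit %s: n = %d, alpha = %.3f, (TP+CR)/2 = %s\n",
                key, x$templates[[key]]$n_spikes_used, a$alpha,
                if (is.na(a$objective_value)) "NA"
                else sprintf("%.3f", a$objective_value)))
  }
  invisible(x)
}

#' @export
coef.ntm <- function(object, ...) {
  vapply(object$alphas, function(a) a$alpha, 0)
}

#' @export
summary.ntm <- function(object, ...) {
  feats <- t(vapply(object$templates, function(tp)
    waveform_features(tp, fs = tp$fs), numeric(3)))
  qual <- t(vapply(object$quality[names(object$templates)], function(q)
    c(refractory_frac = q$refractory_violation_frac,
      missing_frac = q$missing_frac_estimate), numeric(2)))
  out <- data.frame(unit_id = as.integer(names(object$templates)),
                    n_spikes = vapply(object$templates,
                                      function(tp) tp$n_spikes_used, 0L),
                    alpha = coef(object),
                    objective = vapply(object$alphas,
                                       function(a) a$objective_value, 0),
                    feats, qual, row.names = NULL)
  class(out) <- c("summary.ntm", "data.frame")
  out
}

#' @export
print.summary.ntm <- function(x, ...) {
  cat("NTM fit summary (one row per accepted template):\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Detect spikes with a fitted NTM model
#'
#' Runs the second detection round: sliding similarity against each fitted
#' template, thresholded at the fitted `alpha_i` with the shadow period,
#' with near-simultaneous cross-template detections merged to the
#' higher-similarity template.
#'
#' @param object an [ntm_fit()] result.
#' @param newdata a [voltage_recording()]; defaults to the training
#'   recording.
#' @param merge_s cross-template merge window (s).
#' @param ... unused.
#' @return A [spike_events()] table (method `"ntm"` or `"tm"`).
#' @export
predict.ntm <- function(object, newdata = NULL, merge_s = 5e-4, ...) {
  rec <- newdata %||% object$rec
  if (length(object$templates) == 0) {
    warning("no templates in fit; returning empty event table")
    return(spike_events(method = object$kind))
  }
  res <- run_second_round(rec, object$templates,
                          object$first_round$clips, object$first_round$labels,
                          cfg = object$config, kind = object$kind,
                          tetrode = object$channels, merge_s = merge_s)
  res$events
}

#' Plot fitted templates
#'
#' One panel per template, overlaying the per-channel mean waveforms.
#'
#' @param x an [ntm_fit()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ntm <- function(x, ...) {
  k <- length(x$templates)
  if (k == 0) stop("no templates to plot")
  old <- par(mfrow = c(1, k), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (key in names(x$templates)) {
    tp <- x$templates[[key]]
    t_ms <- (seq_len(nrow(tp$mu_mat)) - 1 - tp$pre_samples) / tp$fs * 1000
    matplot(t_ms, tp$mu_mat, type = "l", lty = 1,
            xlab = "time from trough (ms)", ylab = "voltage (uV)",
            main = paste("unit", key), ...)
    abline(v = 0, col = "grey70", lty = 3)
  }
  invisible(x)
}
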