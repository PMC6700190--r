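#' Sliding similarity between a recording and a template
#'
#' For every start sample t, the window `V(t)` is the channel-major
#' concatenation of L-sample segments beginning at t on each channel (the
#' window slides through time, not channel). `kind = "tm"` returns the
#' sliding dot product `C_i(t) = V(t) . mu_i` (uV^2); `kind = "ntm"`
#' returns the sliding cosine similarity
#' `S_i(t) = C_i(t) / (||V(t)|| ||mu_i||)`, a unitless statistic bounded in
#' `[-1, 1]` and invariant to multiplicative rescaling of the voltage.
#' Windows with `||V(t)|| = 0` are defined as 0.
#'
#' The window norm uses a rolling sum of squares with periodic exact
#' recomputation so floating-point drift stays negligible.
#'
#' @param rec a [voltage_recording()].
#' @param template a [compute_template()] result.
#' @param kind `"ntm"` (cosine) or `"tm"` (dot product).
#' @param tetrode channels as in [detect_threshold_crossings()]; must match
#'   the channels the template was built on.
#' @param rolling_sumsq optional precomputed `cpp_rolling_sumsq` vector for
#'   these channels (reused across templates for speed).
#' @return An object of class `similarity_trace`: `values` (length
#'   `n_samples - L + 1`), `kind`, `unit_id`, `fs`, `L`, `pre_samples`,
#'   `t0`.
#' @export
sliding_similarity <- function(rec, template, kind = c("ntm", "tm"),
                               tetrode = NULL, rolling_sumsq = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "voltage_recording"),
            inherits(template, "spike_template"))
  ch <- channel_indices(tetrode, rec)
  if (length(ch) != ncol(template$mu_mat))
    stop("channel count differs between recording selection and template")
  if (nrow(rec$data) < nrow(template$mu_mat))
    stop("trace shorter than template")
  mu_norm <- sqrt(sum(template$mu^2))
  if (mu_norm == 0) stop("zero-norm template")
  V <- select_channels(rec$data, ch)
  C <- cpp_sliding_dot(V, template$mu_mat)
  if (kind == "ntm") {
    q <- rolling_sumsq %||% cpp_rolling_sumsq(V, nrow(template$mu_mat))
    vals <- C / (sqrt(q) * mu_norm)
    vals[q == 0] <- 0
  } else {
    vals <- C
  }
  structure(list(values = vals, kind = kind, unit_id = template$unit_id,
                 fs = rec$fs, L = nrow(template$mu_mat),
                 pre_samples = template$pre_samples, t0 = rec$t0),
            class = "similarity_trace")
}

#' @export
print.similarity_trace <- function(x, ...) {
  cat(sprintf("<similarity_trace> %s, unit %d, %d samples, range [%.3g, %.3g]\n",
              toupper(x$kind), x$unit_id, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Cosine similarity between one clip and a template
#'
#' `S_it = (E_t . mu_i) / (||E_t|| ||mu_i||)` for a voltage clip `E_t`
#' flattened channel-major to length `L*N`. A zero-norm clip yields 0 with
#' a warning.
#'
#' @param clip `L x N` matrix or flattened vector.
#' @param template a [compute_template()] result.
#' @return Similarity in `[-1, 1]`.
#' @export
clip_similarity <- function(clip, template) {
  stopifnot(inherits(template, "spike_template"))
  cosine_sim(as.vector(clip), template$mu, warn_zero = TRUE)
}

#' Choose a detection threshold by the ROC rule
#'
#' Candidate thresholds are every observed similarity value; for each
#' candidate `a`, `TP` is the fraction of target-cluster similarities
#' `>= a` and `CR` the fraction of the remaining (other-cluster plus
#' multi-unit) similarities `< a`. The returned threshold maximizes
#' `(TP + CR) / 2`, breaking ties toward the largest threshold. The argmax
#' is piecewise-constant between observed values, so the observed-values
#' grid is lossless.
#'
#' @param target_sims similarities of clips assigned to the unit.
#' @param other_sims similarities of all remaining clips.
#' @return An object of class `ntm_threshold`: `alpha`,
#'   `objective_value` (the achieved `(TP+CR)/2`), `tp`, `cr`.
#' @export
fit_roc_threshold <- function(target_sims, other_sims) {
  if (length(target_sims) == 0) stop("empty target similarity set")
  if (length(other_sims) == 0) stop("empty other similarity set")
  cand <- sort(unique(c(target_sims, other_sims)))
  st <- sort(target_sims)
  so <- sort(other_sims)
  nt <- length(st); no <- length(so)
  tp <- (nt - findInterval(cand, st, left.open = TRUE)) / nt  # frac >= a
  cr <- findInterval(cand, so, left.open = TRUE) / no         # frac <  a
  obj <- (tp + cr) / 2
  best <- max(obj)
  i <- max(which(obj >= best - 1e-12))   # ties -> largest alpha
  structure(list(alpha = cand[i], objective_value = obj[i],
                 tp = tp[i], cr = cr[i]),
            class = "ntm_threshold")
}

#' @export
print.ntm_threshold <- function(x, ...) {
  cat(sprintf("<ntm_threshold> alpha = %.4g, (TP+CR)/2 = %.3f (TP %.3f, CR %.3f)\n",
              x$alpha, x$objective_value, x$tp, x$cr))
  invisible(x)
}

#' Detect spikes on a similarity trace
#'
#' Within each contiguous epoch where the similarity is at or above
#' `alpha`, the sample of maximal similarity becomes the event (earliest
#' sample on ties); a shadow clock then censors events closer than
#' `shadow_s` to the previously accepted one. Event times are reported at
#' the alignment point, `window start + clip_pre`, so they are directly
#' comparable with first-round and ground-truth tables.
#'
#' @param sim_trace a [sliding_similarity()] result.
#' @param alpha detection threshold (an [fit_roc_threshold()] object or a
#'   number).
#' @param cfg a [detection_config()] (provides the shadow period).
#' @return A [spike_events()] table with the trace's `kind` as method and
#'   a `sim` column holding the similarity at each event.
#' @export
detect_ntm <- function(sim_trace, alpha,
                       cfg = detection_config(fs = sim_trace$fs)) {
  stopifnot(inherits(sim_trace, "similarity_trace"))
  if (inherits(alpha, "ntm_threshold")) alpha <- alpha$alpha
  idx <- cpp_epoch_peaks(sim_trace$values, alpha, cfg$shadow_samples)
  spike_events(time_s = (idx - 1 + sim_trace$pre_samples) / sim_trace$fs +
                 sim_trace$t0,
               unit_id = sim_trace$unit_id,
               method = sim_trace$kind,
               sim = sim_trace$values[idx])
}

# Merge per-template event streams: among events from different templates
# closer than merge_s, the one with the higher similarity survives.
merge_template_events <- function(event_list, merge_s = 5e-4) {
  ev <- do.call(rbind, lapply(event_list, as.data.frame))
  if (is.null(ev) || nrow(ev) == 0)
    return(spike_events(method = if (length(event_list)) event_list[[1]]$method[0] else "ntm"))
  ev <- ev[order(ev$time_s), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  last <- 1L
  if (nrow(ev) > 1) for (i in 2:nrow(ev)) {
    if (ev$time_s[i] - ev$time_s[last] < merge_s &&
        ev$unit_id[i] != ev$unit_id[last]) {
      if (ev$sim[i] > ev$sim[last]) {
        keep[last] <- FALSE
        last <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      last <- i
    }
  }
  ev <- ev[keep, , drop = FALSE]
  spike_events(ev$time_s, ev$unit_id, ev$method, ev$trial_id, sim = ev$sim)
}

# ROC threshold for one template given clip similarities and labels, with
# the degenerate-case fallback: if no non-target clips exist (e.g.
# noise-free single-unit data), alpha falls just below the weakest target
# similarity so every training clip remains detectable.
roc_alpha_for_unit <- function(sims, labels, unit_id) {
  target <- sims[labels == unit_id]
  other <- sims[labels != unit_id]
  if (length(other) == 0) {
    return(structure(list(alpha = min(target) - 1e-6, objective_value = NA_real_,
                          tp = 1, cr = NA_real_), class = "ntm_threshold"))
  }
  fit_roc_threshold(target, other)
}

#' Run the second (template-matching) round of detection
#'
#' For each template: compute the per-clip similarities of the first-round
#' clips, split them into target (clips labeled as the unit) and other
#' clips, fit the ROC threshold, run sliding detection over the recording,
#' and merge the per-template event streams (detections from different
#' templates closer than `merge_s` collapse to the higher-similarity one).
#'
#' @param rec a [voltage_recording()].
#' @param templates list of [compute_template()] results (only templates
#'   passing the caller's quality gate should be supplied).
#' @param first_clips the aligned first-round `spike_clips`.
#' @param labels unit labels of `first_clips`.
#' @param cfg a [detection_config()].
#' @param kind `"ntm"` or `"tm"`. For TM the ROC machinery is applied to
#'   per-clip dot products, so TM and NTM differ only in normalization.
#' @param tetrode channels as in [detect_threshold_crossings()].
#' @param merge_s cross-template merge window (s).
#' @return List with merged `events`, per-template `alphas`, and
#'   `per_template` event tables.
#' @export
run_second_round <- function(rec, templates, first_clips, labels,
                             cfg = detection_config(fs = rec$fs),
                             kind = c("ntm", "tm"), tetrode = NULL,
                             merge_s = 5e-4) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "voltage_recording"))
  if (length(templates) == 0) {
    warning("no templates supplied; returning empty event table")
    return(list(events = spike_events(method = kind), alphas = list(),
                per_template = list()))
  }
  ch <- channel_indices(tetrode, rec)
  n <- length(first_clips$times)
  flat <- matrix(first_clips$waves, n, first_clips$L * length(first_clips$channels))
  L <- nrow(templates[[1]]$mu_mat)
  q <- cpp_rolling_sumsq(select_channels(rec$data, ch), L)
  alphas <- list()
  per_template <- list()
  for (tp in templates) {
    key <- as.character(tp$unit_id)
    sims <- if (kind == "ntm") clip_similarity_matrix(flat, list(tp))[, 1]
            else as.vector(flat %*% tp$mu)
    alphas[[key]] <- roc_alpha_for_unit(sims, labels, tp$unit_id)
    trace <- sliding_similarity(rec, tp, kind = kind, tetrode = ch,
                                rolling_sumsq = q)
    ev <- detect_ntm(trace, alphas[[key]], cfg)
    if (kind == "tm") {
      # arbitration always compares cosines, which are template-comparable
      idx <- round((ev$time_s - rec$t0) * rec$fs) + 1 - tp$pre_samples
      ev$sim <- ev$sim / (sqrt(q[idx]) * sqrt(sum(tp$mu^2)))
    }
    per_template[[key]] <- ev
  }
  list(events = merge_template_events(per_template, merge_s),
       alphas = alphas, per_template = per_template)
}
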