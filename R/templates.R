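#' Build a per-unit spike template
#'
#' The template of unit i is the pointwise mean of its aligned clips on
#' each channel, concatenated channel-major (channel 1's L samples, then
#' channel 2's, ...) into one `1 x (L*N)` row vector.
#'
#' @param clips an aligned `spike_clips` object.
#' @param labels integer unit labels, one per clip (-1 = multi-unit).
#' @param unit_id the unit to build.
#' @return An object of class `spike_template`: flattened `mu`, the
#'   `L x N` matrix `mu_mat`, `unit_id`, `n_spikes_used`, `fs`,
#'   `pre_samples`.
#' @export
compute_template <- function(clips, labels, unit_id) {
  stopifnot(inherits(clips, "spike_clips"))
  if (length(labels) != length(clips$times))
    stop("one label per clip required")
  sel <- which(labels == unit_id)
  if (length(sel) == 0) stop("no clips labeled for unit ", unit_id)
  w <- clips$waves[sel, , , drop = FALSE]
  mu_mat <- colMeans(w, dims = 1)
  mu <- as.vector(mu_mat)               # column-major == channel-major
  if (sqrt(sum(mu^2)) == 0) stop("degenerate template (norm 0)")
  structure(list(mu = mu, mu_mat = mu_mat, unit_id = as.integer(unit_id),
                 n_spikes_used = length(sel), fs = clips$fs,
                 pre_samples = clips$pre_samples),
            class = "spike_template")
}

#' @export
print.spike_template <- function(x, ...) {
  cat(sprintf("<spike_template> unit %d: %d x %d samples (n = %d, trough %.1f uV)\n",
              x$unit_id, nrow(x$mu_mat), ncol(x$mu_mat), x$n_spikes_used,
              min(x$mu_mat)))
  invisible(x)
}

#' Build templates for all units
#'
#' @inheritParams compute_template
#' @param min_spikes minimum clips a unit needs for a template.
#' @return Named list of [compute_template()] results for every unit label
#'   `>= 0` with at least `min_spikes` clips, ordered by unit id.
#' @export
compute_templates <- function(clips, labels, min_spikes = 1) {
  units <- sort(unique(labels[labels >= 0]))
  units <- units[vapply(units, function(u) sum(labels == u), 0L) >= min_spikes]
  out <- lapply(units, function(u) compute_template(clips, labels, u))
  names(out) <- as.character(units)
  out
}

#' Assign clips to templates by cosine similarity
#'
#' A stand-in for waveform clustering (the second-round pipeline can be
#' coupled with any clusterer): each clip is assigned to the template with
#' the highest cosine similarity, provided that similarity reaches
#' `reject_sim`; otherwise it is labeled -1 (multi-unit). Exact ties break
#' toward the lower unit id.
#'
#' @param clips a `spike_clips` object.
#' @param templates list of [compute_template()] results.
#' @param reject_sim rejection floor on the winning similarity.
#' @return Integer label vector, one per clip.
#' @export
assign_clips <- function(clips, templates, reject_sim = 0.7) {
  stopifnot(inherits(clips, "spike_clips"))
  if (length(templates) == 0) stop("at least one template required")
  ids <- vapply(templates, function(tp) tp$unit_id, 0L)
  ord <- order(ids)
  templates <- templates[ord]
  ids <- ids[ord]
  n <- length(clips$times)
  flat <- matrix(clips$waves, n, clips$L * length(clips$channels))
  sims <- clip_similarity_matrix(flat, templates)
  best <- max.col(sims, ties.method = "first")   # first = lowest unit id
  bestsim <- sims[cbind(seq_len(n), best)]
  labels <- ifelse(bestsim >= reject_sim, ids[best], -1L)
  as.integer(labels)
}

clip_similarity_matrix <- function(flat, templates) {
  cn <- sqrt(rowSums(flat^2))
  sims <- vapply(templates, function(tp) {
    mu <- tp$mu
    s <- as.vector(flat %*% mu) / (cn * sqrt(sum(mu^2)))
    s[cn == 0] <- 0
    s
  }, numeric(nrow(flat)))
  matrix(sims, nrow = nrow(flat))
}

#' Refractory-period violation fraction
#'
#' Fraction of a unit's inter-spike intervals shorter than the refractory
#' criterion (1.5 ms), relative to the total number of spikes. Part of the
#' single-unit quality gate (must stay below 0.5%).
#'
#' @param times sorted spike times (s) of one unit.
#' @param refractory_s violation criterion in seconds.
#' @return Fraction in `[0, 1]`; 0 when fewer than 2 spikes.
#' @export
refractory_violation_frac <- function(times, refractory_s = 0.0015) {
  if (length(times) < 2) return(0)
  times <- sort(times)
  sum(diff(times) < refractory_s) / length(times)
}

#' Estimate the fraction of spikes missed below threshold
#'
#' Detected negative-peak amplitudes are truncated at the detection
#' threshold by construction, so a Gaussian is fitted to the amplitude
#' distribution by truncated maximum likelihood (observations censored at
#' the threshold); the estimated missing fraction is the fitted mass on
#' the sub-threshold side, i.e. above the threshold for negative-going
#' amplitudes. The quality gate requires this to stay below 30%.
#'
#' @param amplitudes negative-peak amplitudes in microvolts (negative
#'   numbers), at least 10 of them.
#' @param threshold_uV detection threshold in microvolts (negative).
#' @param method `"truncated"` (MLE, default) or `"moment"` (plain
#'   mean/SD fit, ignoring truncation).
#' @return Estimated missed fraction in `[0, 1]`.
#' @export
estimate_missing_frac <- function(amplitudes, threshold_uV,
                                  method = c("truncated", "moment")) {
  method <- match.arg(method)
  if (length(amplitudes) < 10) stop("need at least 10 amplitudes")
  if (!(is.numeric(threshold_uV) && threshold_uV < 0))
    stop("threshold_uV must be negative (negative-going spikes)")
  if (method == "moment") {
    mu <- mean(amplitudes); sig <- stats::sd(amplitudes)
    if (sig < 1e-9) { warning("degenerate fit (sigma ~ 0)"); return(0) }
    return(1 - stats::pnorm(threshold_uV, mu, sig))
  }
  obs <- amplitudes[amplitudes <= threshold_uV]
  if (length(obs) < 3 || stats::sd(obs) < 1e-9) {
    warning("degenerate fit (sigma ~ 0); returning 0")
    return(0)
  }
  nll <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    -sum(stats::dnorm(obs, mu, sig, log = TRUE)) +
      length(obs) * stats::pnorm(threshold_uV, mu, sig, log.p = TRUE)
  }
  init <- c(mean(obs), log(stats::sd(obs)))
  fit <- tryCatch(stats::optim(init, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    warning("truncated MLE failed to converge; falling back to moment fit")
    return(estimate_missing_frac(amplitudes, threshold_uV, method = "moment"))
  }
  mu <- fit$par[1]; sig <- exp(fit$par[2])
  if (sig < 1e-9) { warning("degenerate fit (sigma ~ 0)"); return(0) }
  1 - stats::pnorm(threshold_uV, mu, sig)
}

#' Mahalanobis distance of a clip to its cluster
#'
#' Distance of one waveform to the cluster mean under the cluster's
#' covariance. To avoid singular covariance in the full `L*N`-dimensional
#' waveform space, clips are first projected onto the leading principal
#' directions per channel (`n_pc` each, 12 features for a tetrode with the
#' default 3); set `reduce = FALSE` to treat inputs as feature vectors
#' directly.
#'
#' @param clip one clip (`L x N` matrix, flattened vector, or feature
#'   vector when `reduce = FALSE`).
#' @param cluster_clips the cluster's clips: a `spike_clips` object, an
#'   `n x L x N` array, or an `n x p` feature matrix when `reduce = FALSE`.
#' @param n_pc principal components kept per channel.
#' @param reduce apply the per-channel PCA reduction.
#' @return The (non-squared) Mahalanobis distance.
#' @export
mahalanobis_to_cluster <- function(clip, cluster_clips, n_pc = 3,
                                   reduce = TRUE) {
  if (inherits(cluster_clips, "spike_clips")) cluster_clips <- cluster_clips$waves
  if (reduce) {
    dims <- dim(cluster_clips)
    if (length(dims) != 3) stop("cluster_clips must be an n x L x N array")
    n <- dims[1]; L <- dims[2]; N <- dims[3]
    clip <- matrix(clip, L, N)
    feats <- matrix(0, n, n_pc * N)
    cf <- numeric(n_pc * N)
    for (c in seq_len(N)) {
      X <- cluster_clips[, , c]
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pc)
      cols <- (c - 1) * n_pc + seq_len(n_pc)
      feats[, cols] <- pc$x[, seq_len(n_pc)]
      cf[cols] <- (clip[, c] - pc$center) %*% pc$rotation[, seq_len(n_pc)]
    }
  } else {
    feats <- as.matrix(cluster_clips)
    cf <- as.numeric(clip)
  }
  if (nrow(feats) <= ncol(feats))
    stop("cluster must have more clips than feature dimensions; ",
         "reduce dimensionality further (smaller n_pc)")
  S <- stats::cov(feats)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("singular cluster covariance; use stronger reduction or regularize")
  sqrt(stats::mahalanobis(cf, colMeans(feats), S))
}

#' Single-unit quality report
#'
#' Applies the two isolation criteria used to gate candidate single units:
#' refractory violations (< 0.5% of spikes with ISI < 1.5 ms) and the
#' estimated sub-threshold missing fraction (< 30%).
#'
#' @param times the unit's spike times (s).
#' @param amplitudes the unit's negative-peak amplitudes (uV, negative).
#' @param threshold_uV detection threshold (uV, negative).
#' @param max_violation,max_missing the gate cut-offs.
#' @return An object of class `quality_report` with
#'   `refractory_violation_frac`, `missing_frac_estimate`,
#'   `passes_single_unit`.
#' @export
quality_report <- function(times, amplitudes, threshold_uV,
                           max_violation = 0.005, max_missing = 0.30) {
  rv <- refractory_violation_frac(times)
  mf <- if (length(amplitudes) >= 10)
    unname(estimate_missing_frac(unname(amplitudes), unname(threshold_uV)))
  else NA_real_
  structure(list(refractory_violation_frac = rv,
                 missing_frac_estimate = mf,
                 passes_single_unit =
                   rv < max_violation && !is.na(mf) && mf < max_missing),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> violations %.3f%%, missing %.1f%% -> %s\n",
              100 * x$refractory_violation_frac,
              100 * x$missing_frac_estimate,
              if (x$passes_single_unit) "single unit" else "rejected"))
  invisible(x)
}
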