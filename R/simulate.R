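#' Smooth spike trains into an instantaneous spiking probability
#'
#' Convolves a 5 ms box filter with individual binary spike trains (1 ms
#' resolution) and averages across trials, yielding a smooth PSTH that
#' describes instantaneous spiking probability per 1 ms step rather than a
#' firing rate. This is the profile the Bernoulli single-unit generator
#' consumes.
#'
#' @param trains binary matrix, trials x 1-ms steps, for one stimulus.
#' @param width_ms box filter width in ms (>= 1).
#' @return Numeric probability profile in `[0, 1]`, one value per step.
#' @export
smooth_psth_boxfilter <- function(trains, width_ms = 5) {
  if (width_ms < 1) stop("box filter width must be at least 1 ms")
  trains <- as.matrix(trains)
  m <- colMeans(trains)
  w <- as.integer(round(width_ms))
  if (w == 1L) return(m)
  h_l <- (w - 1L) %/% 2L
  filt <- rep(1 / w, w)
  full <- stats::convolve(m, rev(filt), type = "open")
  p <- full[(h_l + 1):(h_l + length(m))]
  pmin(pmax(p, 0), 1)
}

#' Sample a Bernoulli spike train with absolute refractory period
#'
#' Independent Bernoulli draws per 1 ms step with success probability
#' `p_profile[t]`; the probability is forced to zero for `refractory_ms`
#' after each emitted spike, enforcing an absolute refractory period. With
#' `p == 1` throughout, spikes land every `refractory_ms + 1` steps
#' (0, 3, 6, ... ms for the 2 ms default).
#'
#' @param p_profile per-step spike probabilities in `[0, 1]`.
#' @param refractory_ms absolute refractory period in ms.
#' @return Integer spike times in ms (0-based step index).
#' @export
sample_bernoulli_train <- function(p_profile, refractory_ms = 2) {
  if (any(p_profile < 0 | p_profile > 1)) stop("p must lie in [0, 1]")
  u <- stats::runif(length(p_profile))
  cand <- which(u < p_profile)
  enforce_refractory(cand, refractory_ms) - 1L
}

# Keep only candidates at least refractory_ms + 1 steps apart (greedy,
# earliest first). Input and output are 1-based step indices.
enforce_refractory <- function(cand, refractory_ms) {
  if (length(cand) < 2) return(cand)
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] - last > refractory_ms) {
      keep[i] <- TRUE
      last <- cand[i]
    }
  }
  cand[keep]
}

#' Sample multi-unit spikes from an inhomogeneous Poisson process
#'
#' Per-step Poisson counts with mean `lambda_profile[t]`; a step with
#' count k emits k spikes at that step, so multi-unit activity has no
#' refractory period and can produce more than one spike per millisecond.
#'
#' @param lambda_profile per-step means (spikes per 1 ms step), `>= 0`.
#' @return Integer spike times in ms (0-based, with multiplicity).
#' @export
sample_poisson_multiunit <- function(lambda_profile) {
  if (any(lambda_profile < 0)) stop("lambda must be non-negative")
  counts <- stats::rpois(length(lambda_profile), lambda_profile)
  rep.int(seq_along(lambda_profile) - 1L, counts)
}

#' Parametric biphasic spike waveform
#'
#' A synthetic extracellular action potential: a negative Gaussian lobe
#' (the current sink) followed by a delayed, smaller positive lobe (the
#' current source), projected onto the tetrode channels by per-channel
#' amplitude weights so each unit has a distinct spatial footprint.
#'
#' @param fs sampling rate (Hz).
#' @param p2p_uV peak-to-peak amplitude on the dominant channel (uV).
#' @param neg_fwhm_ms width (FWHM) of the negative lobe.
#' @param pos_ratio positive-lobe amplitude as a fraction of the negative.
#' @param pos_fwhm_ms width (FWHM) of the positive lobe.
#' @param lag_ms delay of the positive lobe after the trough.
#' @param weights per-channel amplitude weights (dominant channel first is
#'   not required; the maximum defines the dominant channel).
#' @param duration_ms total waveform support.
#' @param trough_ms trough position within the support.
#' @return List with `wave` (`Lw x N` matrix, uV), `trough_idx` (1-based
#'   row of the trough), `fs`.
#' @export
biphasic_waveform <- function(fs = 31250, p2p_uV = 80, neg_fwhm_ms = 0.25,
                              pos_ratio = 0.4, pos_fwhm_ms = 0.5,
                              lag_ms = 0.4, weights = c(1, 0.55, 0.3, 0.15),
                              duration_ms = 2.4, trough_ms = 0.8) {
  t_ms <- (seq_len(round(fs * duration_ms / 1000)) - 1) / fs * 1000
  sn <- neg_fwhm_ms / 2.355
  sp <- pos_fwhm_ms / 2.355
  shape <- -exp(-(t_ms - trough_ms)^2 / (2 * sn^2)) +
    pos_ratio * exp(-(t_ms - trough_ms - lag_ms)^2 / (2 * sp^2))
  shape <- shape * p2p_uV / (max(shape) - min(shape))
  wave <- outer(shape, weights / max(weights))
  list(wave = wave, trough_idx = which.min(shape), fs = fs)
}

#' Specification of one simulated single unit
#'
#' @param unit_id integer label (>= 0).
#' @param waveform a [biphasic_waveform()] result.
#' @param p_profiles matrix of spike probabilities per 1 ms step, one row
#'   per stimulus id (rows 1..10 = stimuli 0..8 plus sham 9).
#' @param amplitude_cv within-unit multiplicative spike-to-spike amplitude
#'   variability (coefficient of variation of a mean-1 lognormal factor).
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(unit_id, waveform, p_profiles, amplitude_cv = 0.15) {
  p_profiles <- as.matrix(p_profiles)
  if (any(p_profiles < 0 | p_profiles > 1)) stop("p must lie in [0, 1]")
  if (min(waveform$wave) >= 0) stop("waveform must be negative-going")
  structure(list(unit_id = as.integer(unit_id), waveform = waveform,
                 p_profiles = p_profiles, amplitude_cv = amplitude_cv),
            class = "unit_spec")
}

#' Specification of the multi-unit background
#'
#' @param lambda_profiles matrix of Poisson means per 1 ms step, one row
#'   per stimulus id.
#' @param pool list of waveforms (each normalized to a trough of -1) drawn
#'   from independently per spike.
#' @param amp_range_uV range of per-spike trough amplitudes (uV, positive
#'   numbers; near 3-4 noise SD for near-threshold background).
#' @return An object of class `multiunit_spec`.
#' @export
multiunit_spec <- function(lambda_profiles, pool, amp_range_uV = c(30, 40)) {
  lambda_profiles <- as.matrix(lambda_profiles)
  if (any(lambda_profiles < 0)) stop("lambda must be non-negative")
  structure(list(lambda_profiles = lambda_profiles, pool = pool,
                 amp_range_uV = amp_range_uV),
            class = "multiunit_spec")
}

#' Render surrogate tetrode voltage with known spike times
#'
#' Generates independent Gaussian white noise per channel, samples each
#' unit's spike train (stimulus-locked Bernoulli with 2 ms absolute
#' refractory, enforced across trial boundaries) and the multi-unit
#' background (inhomogeneous Poisson), adds 0-1 ms uniform jitter to every
#' spike time (realized as the nearest sample), and linearly adds each
#' spike's waveform -- scaled by its per-spike amplitude factor -- into the
#' noise. Spike probabilities are zeroed in the first and last 2 ms of the
#' recording so every truth spike admits a full clip window.
#'
#' Four independent RNG streams (spike sampling, jitter, amplitude
#' variability, noise) are derived from `seed`, so scenarios differing only
#' in noise share an identical truth table under the same seed.
#'
#' @param units list of [unit_spec()] objects.
#' @param multiunit optional [multiunit_spec()].
#' @param schedule a [stimulus_schedule()]; `trial_start_s` are stimulus
#'   onset times, each trial window opening `onset_offset_s` earlier.
#' @param noise_sd Gaussian noise SD per channel (uV).
#' @param fs sampling rate (Hz).
#' @param n_channels tetrode size.
#' @param trial_len_s trial window length (profiles must have
#'   `trial_len_s * 1000` steps).
#' @param onset_offset_s stimulus onset position within the trial window.
#' @param seed integer seed for all four streams.
#' @return An object of class `surrogate_dataset`: `voltage`
#'   ([voltage_recording()]), `truth` ([spike_events()], method
#'   `"truth"`, multi-unit rows labeled -1), `schedule`, `seed`, and the
#'   generating specs.
#' @export
render_voltage <- function(units, multiunit = NULL, schedule, noise_sd = 10,
                           fs = 31250, n_channels = 4, trial_len_s = 0.6,
                           onset_offset_s = 0.2, seed = 1) {
  n_trials <- nrow(schedule)
  steps <- round(trial_len_s * 1000)
  n_steps <- n_trials * steps
  T_samp <- round(n_trials * trial_len_s * fs)
  for (u in units) {
    if (ncol(u$p_profiles) != steps)
      stop("profile length must equal trial steps (", steps, ")")
    if (max(u$waveform$trough_idx,
            nrow(u$waveform$wave) - u$waveform$trough_idx) > T_samp)
      stop("waveform longer than the recording")
  }
  stim_rows <- schedule$stimulus_id + 1L

  # --- spike sampling stream -------------------------------------------
  unit_trains <- with_seed(derive_seed(seed, 2), {
    lapply(units, function(u) {
      per_trial <- lapply(seq_len(n_trials), function(k) {
        p <- u$p_profiles[stim_rows[k], ]
        if (k == 1L) p[1:2] <- 0
        if (k == n_trials) p[(steps - 1):steps] <- 0
        sample_bernoulli_train(p) + (k - 1L) * steps
      })
      abs_ms <- unlist(per_trial)
      # refractory across trial boundaries (trials are contiguous in time)
      (enforce_refractory(abs_ms + 1L, 2) - 1L)
    })
  })
  mua_ms <- if (is.null(multiunit)) integer(0) else
    with_seed(derive_seed(seed, 7), {
      lam <- as.vector(t(multiunit$lambda_profiles[stim_rows, , drop = FALSE]))
      lam[1:2] <- 0
      lam[(n_steps - 1):n_steps] <- 0
      sample_poisson_multiunit(lam)
    })

  all_ms <- c(unlist(unit_trains), mua_ms)
  unit_of <- c(rep(vapply(units, function(u) u$unit_id, 0L),
                   lengths(unit_trains)),
               rep(-1L, length(mua_ms)))
  n_all <- length(all_ms)

  # --- jitter stream (0-1 ms uniform, realized at the nearest sample) ---
  jit <- with_seed(derive_seed(seed, 3), stats::runif(n_all))
  trough_samp <- round((all_ms + jit) / 1000 * fs) + 1L

  # --- amplitude stream -------------------------------------------------
  amps <- with_seed(derive_seed(seed, 4), {
    a <- numeric(n_all)
    for (u in units) {
      sel <- unit_of == u$unit_id
      cv <- u$amplitude_cv
      a[sel] <- if (cv > 0) {
        sl <- sqrt(log(1 + cv^2))
        stats::rlnorm(sum(sel), meanlog = -sl^2 / 2, sdlog = sl)
      } else 1
    }
    sel <- unit_of == -1L
    if (any(sel) && !is.null(multiunit))
      a[sel] <- stats::runif(sum(sel), multiunit$amp_range_uV[1],
                             multiunit$amp_range_uV[2])
    a
  })
  pool_idx <- if (!is.null(multiunit) && length(mua_ms))
    with_seed(derive_seed(seed, 5),
              sample.int(length(multiunit$pool), length(mua_ms),
                         replace = TRUE))
  else integer(0)

  # --- noise stream -----------------------------------------------------
  V <- with_seed(derive_seed(seed, 6), {
    out <- matrix(0, T_samp, n_channels)
    for (c in seq_len(n_channels))   # per channel, to cap peak memory
      out[, c] <- stats::rnorm(T_samp, 0, noise_sd)
    out
  })

  # --- waveform insertion ----------------------------------------------
  keep <- rep(TRUE, n_all)
  for (u in units) {
    sel <- which(unit_of == u$unit_id)
    starts <- trough_samp[sel] - (u$waveform$trough_idx - 1L)
    ok <- starts >= 1 & starts + nrow(u$waveform$wave) - 1 <= T_samp
    keep[sel[!ok]] <- FALSE
    cpp_add_waveforms(V, starts[ok], amps[sel[ok]], u$waveform$wave)
  }
  if (length(mua_ms)) {
    mua_sel <- which(unit_of == -1L)
    for (pi in unique(pool_idx)) {
      wv <- multiunit$pool[[pi]]
      sel <- mua_sel[pool_idx == pi]
      starts <- trough_samp[sel] - (wv$trough_idx - 1L)
      ok <- starts >= 1 & starts + nrow(wv$wave) - 1 <= T_samp
      keep[sel[!ok]] <- FALSE
      cpp_add_waveforms(V, starts[ok], amps[sel[ok]], wv$wave)
    }
  }

  truth <- spike_events(time_s = (trough_samp[keep] - 1) / fs,
                        unit_id = unit_of[keep], method = "truth",
                        trial_id = findInterval(all_ms[keep],
                                                (seq_len(n_trials) - 1L) * steps))
  structure(list(voltage = voltage_recording(V, fs),
                 truth = truth, schedule = schedule, seed = seed,
                 units = units, multiunit = multiunit, noise_sd = noise_sd,
                 fs = fs, trial_len_s = trial_len_s,
                 onset_offset_s = onset_offset_s),
            class = "surrogate_dataset")
}

#' @export
print.surrogate_dataset <- function(x, ...) {
  su <- sum(x$truth$unit_id >= 0)
  cat(sprintf(paste0("<surrogate_dataset>%s %d trials, %.0f s, %d channels @ %g Hz\n",
                     "  %d single-unit + %d multi-unit truth spikes, noise SD %g uV, seed %d\n"),
              if (is.null(attr(x, "scenario"))) "" else
                paste0(" [", attr(x, "scenario"), "]"),
              nrow(x$schedule), nrow(x$schedule) * x$trial_len_s,
              ncol(x$voltage$data), x$fs,
              su, nrow(x$truth) - su, x$noise_sd, x$seed))
  invisible(x)
}

#' Build a benchmark scenario
#'
#' The in-silico benchmark substrate: 100 trials of each of 9 whisker
#' stimuli plus 100 sham trials (600 ms windows, stimulus onset 200 ms into
#' the window), a 4-channel tetrode at 31.25 kHz with 10 uV Gaussian noise,
#' 5 single units with evenly spaced mean peak-to-peak amplitudes
#' 50-110 uV (population mean 80 uV), 15% within-unit amplitude CV,
#' Gaussian stimulus tuning with staggered preferred whiskers, evoked
#' probability peaking within 30 ms of stimulus onset and a mean unit rate
#' near 3 Hz, plus a near-threshold (30-40 uV) Poisson multi-unit
#' background averaging ~30 Hz in the post-stimulus window. `"noise_x5"`
#' quintuples the noise SD (identical truth table under the same seed);
#' `"rate_x5"` quintuples all Bernoulli probabilities (clipped at 1) and
#' Poisson means.
#'
#' @param name `"baseline"`, `"noise_x5"` or `"rate_x5"`.
#' @param seed integer seed (drives all generator streams).
#' @param n_trials_per_stim trials per stimulus (100 for the full-size
#'   benchmark; smaller values give a short recording with the same
#'   statistics).
#' @param fs sampling rate (Hz).
#' @param noise_sd baseline noise SD (uV).
#' @param n_units number of single units (amplitudes evenly spaced over
#'   50-110 uV).
#' @return A [render_voltage()] result with a `"scenario"` attribute.
#' @export
make_benchmark_scenario <- function(name = c("baseline", "noise_x5", "rate_x5"),
                                    seed = 1, n_trials_per_stim = 100,
                                    fs = 31250, noise_sd = 10, n_units = 5) {
  name <- match.arg(name)
  rate_mult <- if (name == "rate_x5") 5 else 1
  if (name == "noise_x5") noise_sd <- 5 * noise_sd

  trial_len_s <- 0.6
  steps <- 600L
  stim_ids <- with_seed(derive_seed(seed, 1),
                        sample(rep(0:9, each = n_trials_per_stim)))
  n_trials <- length(stim_ids)
  schedule <- stimulus_schedule((seq_len(n_trials) - 1) * trial_len_s + 0.2,
                                stim_ids)

  # evoked temporal profile: alpha function peaking 10 ms after onset
  bump <- function(tau) {
    b <- numeric(steps)
    t_rel <- 0:119
    b[201:320] <- (t_rel / tau) * exp(1 - t_rel / tau)
    b
  }
  p2p <- seq(50, 110, length.out = n_units)
  prefs <- round(seq(0, 8, length.out = n_units))
  base_w <- c(1, 0.55, 0.3, 0.15)
  units <- lapply(seq_len(n_units), function(i) {
    dom <- (i - 1L) %% 4L + 1L
    w <- base_w[((seq_len(4) - dom) %% 4) + 1]
    wf <- biphasic_waveform(fs, p2p_uV = p2p[i],
                            neg_fwhm_ms = 0.22 + 0.015 * i,
                            pos_ratio = 0.35 + 0.02 * i,
                            pos_fwhm_ms = 0.45 + 0.02 * i,
                            lag_ms = 0.35 + 0.02 * i,
                            weights = w)
    tuning <- exp(-((0:8) - prefs[i])^2 / (2 * 1.5^2))
    pb <- bump(10)
    p <- matrix(0.002, nrow = 10, ncol = steps)   # 2 Hz spontaneous
    for (s in 1:9) p[s, ] <- p[s, ] + 0.074 * tuning[s] * pb
    p <- pmin(p * rate_mult, 1)
    unit_spec(i, wf, p, amplitude_cv = 0.15)
  })

  pool <- with_seed(derive_seed(seed, 8), {
    lapply(seq_len(64), function(j) {
      dom <- sample.int(4, 1)
      w <- c(1, sort(stats::runif(3, 0.1, 0.7), decreasing = TRUE))
      wf <- biphasic_waveform(fs, p2p_uV = 1,
                              neg_fwhm_ms = stats::runif(1, 0.2, 0.35),
                              pos_ratio = stats::runif(1, 0.3, 0.5),
                              pos_fwhm_ms = stats::runif(1, 0.4, 0.6),
                              lag_ms = stats::runif(1, 0.3, 0.5),
                              weights = w[((seq_len(4) - dom) %% 4) + 1])
      wf$wave <- wf$wave / (-min(wf$wave))   # trough -1; uV amp per spike
      wf
    })
  })
  lam <- matrix(0.012, nrow = 10, ncol = steps)   # 12 Hz background
  mb <- bump(15)
  for (s in 1:9) lam[s, ] <- lam[s, ] + 0.055 * mb
  mua <- multiunit_spec(lam * rate_mult, pool, amp_range_uV = c(30, 40))

  ds <- render_voltage(units, mua, schedule, noise_sd = noise_sd, fs = fs,
                       trial_len_s = trial_len_s, onset_offset_s = 0.2,
                       seed = seed)
  attr(ds, "scenario") <- name
  ds
}
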