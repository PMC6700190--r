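# Small in-code fixtures shared across test files.

# A quiet multichannel carrier whose SD is well defined but which never
# crosses a 3 SD threshold on its own (deterministic sine).
sine_channel <- function(n, amp = 2, period = 50) {
  amp * sin(2 * pi * seq_len(n) / period)
}

# Recording with biphasic dips inserted on channel 1 at given samples.
make_dip_recording <- function(dip_samples, n = 4000, fs = 31250,
                               amp = -60, n_channels = 2) {
  x <- rep(0, n)
  for (s in dip_samples) x[s + 0:2] <- c(0.6, 1, 0.4) * amp
  V <- cbind(x, vapply(seq_len(n_channels - 1),
                       function(i) sine_channel(n, period = 40 + 10 * i),
                       numeric(n)))
  voltage_recording(V, fs = fs)
}

# Bare-bones template from an explicit L x N matrix.
make_template <- function(mu_mat, fs = 31250, unit_id = 1L,
                          pre_samples = NULL) {
  mu_mat <- as.matrix(mu_mat)
  structure(list(mu = as.vector(mu_mat), mu_mat = mu_mat,
                 unit_id = as.integer(unit_id), n_spikes_used = 1L,
                 fs = fs,
                 pre_samples = pre_samples %||% as.integer(round(fs * 5e-4))),
            class = "spike_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Explicit-loop cosine similarity oracle for the sliding statistic.
brute_sliding_cosine <- function(V, mu_mat) {
  T_ <- nrow(V); L <- nrow(mu_mat)
  mu <- as.vector(mu_mat)
  vapply(seq_len(T_ - L + 1), function(t) {
    v <- as.vector(V[t:(t + L - 1), , drop = FALSE])
    nv <- sqrt(sum(v^2)); nm <- sqrt(sum(mu^2))
    if (nv == 0) 0 else sum(v * mu) / (nv * nm)
  }, numeric(1))
}

# Naive per-sample threshold-crossing scan honoring the shadow period.
brute_crossings <- function(V, thr, shadow_samples) {
  hits <- integer(0)
  last <- -Inf
  for (t in 2:nrow(V)) {
    if (t - 1 - last <= shadow_samples) next
    if (any(V[t, ] < thr & V[t - 1, ] >= thr)) {
      hits <- c(hits, t)
      last <- t - 1
    }
  }
  hits
}

# Single-unit surrogate helper used by detection and recovery tests.
small_single_unit_dataset <- function(seed = 1, n_trials = 20,
                                      noise_sd = 0, amplitude_cv = 0,
                                      p2p = 80, fs = 31250) {
  wf <- biphasic_waveform(fs, p2p_uV = p2p)
  p <- matrix(0.003, nrow = 10, ncol = 600)
  p[1:9, 201:230] <- 0.05
  u <- unit_spec(1L, wf, p, amplitude_cv = amplitude_cv)
  sched <- stimulus_schedule((seq_len(n_trials) - 1) * 0.6 + 0.2,
                             rep(c(0:8, 9L), length.out = n_trials))
  render_voltage(list(u), NULL, sched, noise_sd = noise_sd, fs = fs,
                 seed = seed)
}
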