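test_that("box-filter PSTH smoothing matches explicit convolution", {
  expect_equal(smooth_psth_boxfilter(matrix(0, 10, 100)), rep(0, 100))

  # one spike at step 51 in 1 of 10 trials: 5 ms plateau of 1/5 / 10
  tr <- matrix(0, 10, 100)
  tr[1, 51] <- 1
  p <- smooth_psth_boxfilter(tr, 5)
  expect_equal(p[49:53], rep(0.02, 5), tolerance = 1e-9)
  expect_equal(sum(p > 1e-9), 5)

  # the same spike in every trial: plateau at 1/5
  tr2 <- matrix(0, 10, 100); tr2[, 51] <- 1
  p2 <- smooth_psth_boxfilter(tr2, 5)
  expect_equal(p2[49:53], rep(0.2, 5), tolerance = 1e-9)

  # general case against a direct convolution oracle
  set.seed(51)
  tr3 <- matrix(rbinom(500, 1, 0.1), 5, 100)
  p3 <- smooth_psth_boxfilter(tr3, 5)
  m <- colMeans(tr3)
  oracle <- vapply(1:100, function(t)
    mean(m[max(1, t - 2):min(100, t + 2)]) *
      length(max(1, t - 2):min(100, t + 2)) / 5, 0)
  expect_equal(p3, oracle, tolerance = 1e-9)

  expect_error(smooth_psth_boxfilter(tr, 0.5), "at least 1")
})

test_that("Bernoulli trains honour the absolute refractory period", {
  set.seed(52)
  expect_length(sample_bernoulli_train(rep(0, 500)), 0)
  # p == 1: one spike every 3 ms exactly
  t1 <- sample_bernoulli_train(rep(1, 30))
  expect_equal(t1, seq(0, 27, by = 3))
  # never an ISI below refractory + 1 steps
  t2 <- sample_bernoulli_train(rep(0.4, 5000))
  expect_true(all(diff(t2) >= 3))
  # constant low p recovers the nominal rate within 3 SE
  t3 <- sample_bernoulli_train(rep(0.003, 200000))   # 200 s at 3 Hz
  se <- sqrt(0.003 * 200000)
  expect_lt(abs(length(t3) - 600), 3 * se)
})

test_that("Poisson multi-unit spikes have the right mean and multiplicity", {
  set.seed(53)
  expect_length(sample_poisson_multiunit(rep(0, 100)), 0)
  s <- sample_poisson_multiunit(rep(0.04, 100000))   # 100 s
  expect_lt(abs(length(s) - 4000), 3 * sqrt(4000))
  # a large-lambda step emits several spikes (no refractory)
  s2 <- sample_poisson_multiunit(c(0, 20, 0))
  expect_gt(sum(s2 == 1), 1)
  expect_error(sample_poisson_multiunit(c(-1, 0)), "non-negative")
})

test_that("rendered voltage is noise plus inserted waveforms exactly", {
  # no units: pure Gaussian noise at the requested SD
  sched <- stimulus_schedule(c(0.2, 0.8), c(0L, 9L))
  empty <- render_voltage(list(), NULL, sched, noise_sd = 10, seed = 4)
  expect_equal(unname(estimate_noise_sd(empty$voltage)$sd_per_channel),
               rep(10, 4), tolerance = 0.1)

  # noise-free: subtracting every inserted waveform leaves exactly zero
  ds <- small_single_unit_dataset(seed = 5, n_trials = 10)
  expect_gt(nrow(ds$truth), 20)
  V <- ds$voltage$data
  wf <- ds$units[[1]]$waveform
  for (i in seq_len(nrow(ds$truth))) {
    s0 <- round(ds$truth$time_s[i] * ds$fs) + 1 - (wf$trough_idx - 1)
    V[s0:(s0 + nrow(wf$wave) - 1), ] <-
      V[s0:(s0 + nrow(wf$wave) - 1), ] - wf$wave
  }
  expect_equal(max(abs(V)), 0)

  # superposition: two overlapping waveforms add linearly
  p_hi <- matrix(0, 10, 600); p_hi[, 300] <- 1; p_hi[, 303] <- 1
  u <- unit_spec(1L, biphasic_waveform(31250), p_hi, amplitude_cv = 0)
  one <- render_voltage(list(u), NULL,
                        stimulus_schedule(0.2, 0L), noise_sd = 0, seed = 6)
  expect_equal(nrow(one$truth), 2)
  peak_sum <- sum(abs(range(one$voltage$data[, 1])))
  expect_gt(peak_sum, sum(abs(range(u$waveform$wave[, 1]))) * 0.9)
})

test_that("no single-unit ISI in any truth table violates the refractory", {
  for (seed in 1:3) {
    ds <- small_single_unit_dataset(seed = seed, n_trials = 10,
                                    noise_sd = 5, amplitude_cv = 0.15)
    isi <- diff(ds$truth$time_s[ds$truth$unit_id == 1])
    expect_gt(min(isi), 0.002)
  }
})

test_that("benchmark scenarios are reproducible and share spike streams", {
  ds1 <- make_benchmark_scenario("baseline", seed = 9, n_trials_per_stim = 2)
  ds2 <- make_benchmark_scenario("baseline", seed = 9, n_trials_per_stim = 2)
  expect_identical(ds1$voltage$data, ds2$voltage$data)
  expect_identical(ds1$truth, ds2$truth)

  # quintupled noise leaves the truth table untouched under the same seed
  dn <- make_benchmark_scenario("noise_x5", seed = 9, n_trials_per_stim = 2)
  expect_identical(as.data.frame(dn$truth), as.data.frame(ds1$truth))
  expect_equal(dn$noise_sd, 50)
  expect_false(identical(dn$voltage$data, ds1$voltage$data))

  # a different seed changes the realization
  ds3 <- make_benchmark_scenario("baseline", seed = 10, n_trials_per_stim = 2)
  expect_false(identical(ds3$truth$time_s, ds1$truth$time_s))

  expect_error(make_benchmark_scenario("nope"), "arg")
})

test_that("scenario rates match their configured profiles", {
  ds <- make_benchmark_scenario("baseline", seed = 1, n_trials_per_stim = 12)
  dur <- nrow(ds$schedule) * 0.6
  su <- ds$truth[ds$truth$unit_id >= 0, ]
  rate <- nrow(su) / dur / length(unique(su$unit_id))
  expect_gt(rate, 2); expect_lt(rate, 4)

  dr <- make_benchmark_scenario("rate_x5", seed = 1, n_trials_per_stim = 12)
  sur <- dr$truth[dr$truth$unit_id >= 0, ]
  rate5 <- nrow(sur) / dur / length(unique(sur$unit_id))
  expect_gt(rate5 / rate, 3.5)              # ~5x, refractory saturation allowed
  expect_lt(rate5 / rate, 5.5)

  # multi-unit background present and near threshold
  mu <- ds$truth[ds$truth$unit_id == -1, ]
  expect_gt(nrow(mu) / dur, 5)
})
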