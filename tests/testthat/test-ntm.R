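test_that("sliding similarity equals the explicit-loop cosine oracle", {
  set.seed(41)
  for (i in 1:25) {
    L <- sample(2:5, 1); N <- sample(1:3, 1); T_ <- sample((L + 2):120, 1)
    V <- matrix(rnorm(T_ * N), T_, N)
    mu <- matrix(rnorm(L * N), L, N)
    rec <- voltage_recording(V, fs = 1000)
    tp <- make_template(mu, fs = 1000, pre_samples = 1L)
    s <- sliding_similarity(rec, tp, "ntm")
    expect_equal(s$values, brute_sliding_cosine(V, mu), tolerance = 1e-12)
    expect_lte(max(abs(s$values)), 1 + 1e-12)
    # positive rescaling of the voltage leaves the cosine untouched
    s2 <- sliding_similarity(voltage_recording(V * 7.3, fs = 1000), tp, "ntm")
    expect_lt(max(abs(s2$values - s$values)), 1e-10)
    # TM is the plain sliding dot product
    ctm <- sliding_similarity(rec, tp, "tm")
    expect_equal(ctm$values[1], sum(V[1:L, ] * mu))
  }
})

test_that("a trace containing the template scores exactly 1 at its offset", {
  set.seed(42)
  mu <- matrix(rnorm(47 * 4, sd = 20), 47, 4)
  V <- matrix(0, 2000, 4)
  V[500:546, ] <- mu
  rec <- voltage_recording(V, fs = 31250)
  tp <- make_template(mu)
  s <- sliding_similarity(rec, tp, "ntm")
  expect_equal(s$values[500], 1, tolerance = 1e-12)
  # scale invariance at the spike, and the TM identity C = 5 ||mu||^2
  rec5 <- voltage_recording(V * 5, fs = 31250)
  expect_equal(sliding_similarity(rec5, tp, "ntm")$values[500], 1,
               tolerance = 1e-12)
  expect_equal(sliding_similarity(rec5, tp, "tm")$values[500],
               5 * sum(mu^2), tolerance = 1e-9)
  # zero-energy windows are defined as 0
  expect_equal(s$values[1500], 0)
  expect_error(sliding_similarity(rec, make_template(matrix(0, 47, 4))),
               "zero-norm")
})

test_that("clip similarity is the flattened-cosine formula", {
  tp <- make_template(matrix(c(4, 3, 2, 1), 4, 1))
  expect_equal(clip_similarity(c(1, 2, 3, 4), tp), 20 / 30)
  expect_equal(clip_similarity(tp$mu, tp), 1)
  expect_equal(clip_similarity(-tp$mu, tp), -1)
  expect_warning(s0 <- clip_similarity(rep(0, 4), tp), "zero-norm")
  expect_equal(s0, 0)
})

test_that("the ROC threshold maximizes (TP+CR)/2 over observed values", {
  r <- fit_roc_threshold(c(0.90, 0.95), c(0.10, 0.20))
  expect_equal(r$alpha, 0.90)
  expect_equal(r$objective_value, 1.0)

  same <- fit_roc_threshold(c(0.3, 0.5, 0.7), c(0.3, 0.5, 0.7))
  expect_equal(same$objective_value, 0.5)

  inverted <- fit_roc_threshold(0.8, 0.9)
  expect_equal(inverted$objective_value, 0.5)

  expect_error(fit_roc_threshold(numeric(0), 1), "empty")
  expect_error(fit_roc_threshold(1, numeric(0)), "empty")

  # equals an exhaustive dense-grid scan on random instances
  set.seed(43)
  for (i in 1:30) {
    tg <- runif(sample(1:20, 1)); ot <- runif(sample(1:20, 1))
    r <- fit_roc_threshold(tg, ot)
    grid <- seq(-0.01, 1.01, by = 1e-3)
    obj <- vapply(grid, function(a)
      (mean(tg >= a) + mean(ot < a)) / 2, 0)
    expect_equal(r$objective_value, max(obj), tolerance = 1e-9)
  }
})

test_that("similarity-trace detection picks epoch peaks under a shadow", {
  fs <- 31250
  mk_trace <- function(vals) structure(
    list(values = vals, kind = "ntm", unit_id = 1L, fs = fs, L = 47L,
         pre_samples = 16L, t0 = 0), class = "similarity_trace")
  cfg <- detection_config(fs = fs)

  expect_equal(nrow(detect_ntm(mk_trace(rep(0.1, 5000)), 0.8, cfg)), 0)

  v <- rep(0, 5000)
  v[998:1002] <- c(0.82, 0.9, 0.95, 0.9, 0.82)   # peak at sample 1000
  ev <- detect_ntm(mk_trace(v), 0.8, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(round(ev$time_s * fs) + 1, 1000 + 16)
  expect_equal(ev$sim, 0.95)

  # two bumps 0.3 ms apart (~9 samples): second shadowed
  v2 <- rep(0, 5000); v2[1000] <- 0.9; v2[1009] <- 0.9
  expect_equal(nrow(detect_ntm(mk_trace(v2), 0.8, cfg)), 1)
  # 1 ms apart: both survive
  v3 <- rep(0, 5000); v3[1000] <- 0.9; v3[1031] <- 0.9
  expect_equal(nrow(detect_ntm(mk_trace(v3), 0.8, cfg)), 2)
})

test_that("the second round recovers every truth spike on noise-free data", {
  ds <- small_single_unit_dataset(seed = 2, n_trials = 10)
  rec <- ds$voltage
  cfg <- detection_config(fs = ds$fs)
  ev <- detect_threshold_crossings(rec, cfg = cfg)
  clips <- align_clips(extract_clips(rec, ev, cfg), rec)
  labels <- rep(1L, length(clips$times))
  tp <- compute_template(clips, labels, 1L)
  res <- run_second_round(rec, list(tp), clips, labels, cfg)
  expect_equal(nrow(res$events), nrow(ds$truth))
  m <- match_detections_to_truth(res$events, ds$truth, tol_s = 2e-4)
  expect_equal(m$per_unit$detection_fraction, 1.0)
  expect_equal(m$n_false_alarms, 0)
})

test_that("an empty template list warns and returns no events", {
  ds <- small_single_unit_dataset(seed = 3, n_trials = 2)
  cfg <- detection_config(fs = ds$fs)
  cl <- structure(list(waves = array(0, c(0, 47, 4)), times = numeric(0),
                       start_samples = integer(0), fs = ds$fs, L = 47L,
                       pre_samples = 16L, channels = 1:4, aligned = TRUE),
                  class = "spike_clips")
  expect_warning(res <- run_second_round(ds$voltage, list(), cl, integer(0),
                                         cfg), "no templates")
  expect_equal(nrow(res$events), 0)
})

test_that("near-simultaneous cross-template detections merge to the higher cosine", {
  e1 <- spike_events(c(0.100, 0.200), 1L, "ntm", sim = c(0.9, 0.8))
  e2 <- spike_events(c(0.1002, 0.300), 2L, "ntm", sim = c(0.95, 0.7))
  merged <- ntmdetect:::merge_template_events(list(e1, e2), merge_s = 5e-4)
  expect_equal(nrow(merged), 3)
  expect_equal(merged$unit_id[merged$time_s == 0.1002], 2L)
  expect_false(0.100 %in% merged$time_s)
})
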