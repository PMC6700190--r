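test_that("near-simultaneous filtering removes cross-unit pairs only", {
  tr <- spike_events(c(0.1000, 0.1003, 0.2, 0.3, 0.3007, 0.5, 0.5002),
                     unit_id = c(1L, 2L, 1L, 1L, 2L, 1L, -1L),
                     method = "truth")
  out <- drop_near_simultaneous(tr)
  # 0.1000/0.1003 (units 1 vs 2, 0.3 ms) both removed;
  # 0.3/0.3007 are 0.7 ms apart -> kept; unit/multi-unit pair kept
  expect_equal(nrow(out), 5)
  expect_false(any(out$time_s %in% c(0.1000, 0.1003)))
  expect_true(all(c(0.3, 0.3007, 0.5, 0.5002) %in% out$time_s))
  expect_equal(attr(out, "dropped_fraction"), 2 / 6)

  # same-unit spikes inside the window are kept (rule is between units)
  same <- spike_events(c(0.1, 0.1003), unit_id = 1L, method = "truth")
  expect_equal(nrow(drop_near_simultaneous(same)), 2)
})

test_that("greedy one-to-one matching attributes and conserves counts", {
  truth <- spike_events(c(0.1, 0.2, 0.3), unit_id = c(1L, 1L, 2L),
                        method = "truth")
  # identical tables: perfect score
  m <- match_detections_to_truth(spike_events(c(0.1, 0.2, 0.3)), truth,
                                 tol_s = 5e-4)
  expect_equal(m$per_unit$detection_fraction, c(1, 1))
  expect_equal(m$n_false_alarms, 0)

  # 0.4 ms away matches at 0.5 ms tolerance, 0.6 ms does not
  m2 <- match_detections_to_truth(spike_events(c(0.1004, 0.2006)), truth,
                                  tol_s = 5e-4)
  expect_equal(m2$per_unit$tp[m2$per_unit$unit_id == 1], 1)
  expect_equal(m2$per_unit$miss[m2$per_unit$unit_id == 1], 1)

  # two detections for one truth spike: one TP plus one false alarm
  m3 <- match_detections_to_truth(spike_events(c(0.1, 0.10025)), truth,
                                  tol_s = 5e-4)
  expect_equal(sum(m3$per_unit$tp), 1)
  expect_equal(m3$n_false_alarms, 1)

  # conservation: TP + misses = truth count, per unit
  set.seed(61)
  det <- spike_events(sort(runif(50)))
  big <- spike_events(sort(runif(80)), unit_id = sample(0:3, 80, TRUE),
                      method = "truth")
  m4 <- match_detections_to_truth(det, big, tol_s = 5e-4)
  expect_equal(m4$per_unit$tp + m4$per_unit$miss, m4$per_unit$n_truth)
  expect_equal(sum(m4$per_unit$n_truth),
               sum(big$unit_id >= 0))

  # invariance to a global time shift of both tables
  m5 <- match_detections_to_truth(
    spike_events(det$time_s + 5),
    spike_events(big$time_s + 5, big$unit_id, "truth"), tol_s = 5e-4)
  expect_equal(m5$per_unit, m4$per_unit)
})

test_that("miss causes partition into shadowed and sub-threshold", {
  # shadowed: a large spike 0.3 ms after a detected event
  rec <- make_dip_recording(c(500, 510))
  cfg <- detection_config(fs = 31250)
  ev <- detect_threshold_crossings(rec, cfg = cfg)
  expect_equal(nrow(ev), 1)
  cause <- classify_miss_cause((510 + 1 - 1) / 31250, rec, ev, cfg)
  expect_equal(as.character(cause), "shadowed")

  # sub-threshold: a dip too small to reach the threshold, no prior event
  rec2 <- make_dip_recording(500)
  sd1 <- estimate_noise_sd(rec2)$sd_per_channel[1]
  small <- rec2
  small$data[1500 + 0:2, 1] <- -2 * sd1 * c(0.6, 1, 0.4)   # 2 SD dip
  ev2 <- detect_threshold_crossings(small, cfg = cfg)
  cause2 <- classify_miss_cause((1501 - 1) / 31250, small, ev2, cfg)
  expect_equal(as.character(cause2), "sub_threshold")

  expect_length(classify_miss_cause(numeric(0), rec, ev, cfg), 0)
})

test_that("PSTHs count trial-averaged rates in the right bins", {
  sched <- stimulus_schedule(seq(0.2, by = 0.6, length.out = 100),
                             rep(c(3L, 9L), 50))
  # one spike 5 ms after onset of every stimulus-3 trial
  on3 <- sched$trial_start_s[sched$stimulus_id == 3]
  ev <- spike_events(on3 + 0.005)
  h <- psth(ev, sched, bin_ms = 10)
  r3 <- h[rownames(h) == "3", ]
  centers <- attr(h, "bin_centers_s")
  expect_equal(r3[which(centers > 0 & centers < 0.01)], 100,
               ignore_attr = TRUE)
  expect_equal(sum(r3), 100)
  expect_true(all(h[rownames(h) == "9", ] == 0))

  expect_true(all(psth(spike_events(), sched) == 0))
})

test_that("evoked and spontaneous rates follow the 125 ms window rule", {
  sched <- stimulus_schedule(seq(0.2, by = 0.6, length.out = 40),
                             rep(c(3L, 9L), 20))
  on3 <- sched$trial_start_s[sched$stimulus_id == 3]
  # 2 spikes in-window every stimulus-3 trial -> 2 / 0.125 = 16 Hz
  ev <- spike_events(sort(c(on3 + 0.010, on3 + 0.050)))
  r <- evoked_rate(ev, sched)
  expect_equal(unname(r$evoked["3"]), 16)
  expect_equal(r$spontaneous, 0)

  # spikes at +200 ms fall outside the window
  late <- evoked_rate(spike_events(on3 + 0.2), sched)
  expect_equal(unname(late$evoked["3"]), 0)

  empty <- evoked_rate(spike_events(), sched)
  expect_true(all(empty$evoked == 0))

  noSham <- stimulus_schedule(c(0.2, 0.8), c(1L, 2L))
  expect_warning(r2 <- evoked_rate(ev, noSham), "sham")
  expect_true(is.na(r2$spontaneous))
})

test_that("percent gain and ranked receptive fields are plain arithmetic", {
  expect_equal(percent_gain(1.5, 1.0), 50)
  expect_equal(percent_gain(2, 2), 0)
  expect_true(is.na(percent_gain(1, 0)))
  expect_equal(percent_gain(c(1.5, 2), c(1, 0)), c(50, NA))

  expect_equal(ranked_receptive_field(c(1, 3, 2)), c(3, 2, 1))
  expect_equal(unname(ranked_receptive_field(c(2, 2, 2))), c(2, 2, 2))
  m <- rbind(c(1, 3, 2), c(5, 4, 6))
  rr <- ranked_receptive_field(m)
  expect_equal(unname(rr), c((3 + 6) / 2, (2 + 5) / 2, (1 + 4) / 2),
               ignore_attr = TRUE)
  expect_equal(unname(attr(rr, "per_unit")[1, ]), c(3, 2, 1))
})

test_that("waveform features read the dominant-channel biphasic shape", {
  fs <- 31250
  t_ms <- (0:74) / fs * 1000
  w <- -80 * exp(-(t_ms - 0.5)^2 / (2 * 0.1^2)) +
    30 * exp(-(t_ms - 0.9)^2 / (2 * 0.15^2))
  m <- cbind(w, 0.3 * w)
  f <- waveform_features(m, fs = fs)
  expect_equal(unname(f["neg_amplitude_uV"]), min(w), tolerance = 1e-6)
  expect_equal(unname(f["pos_peak_uV"]), max(w[t_ms > 0.5]), tolerance = 1e-6)
  expect_lt(abs(unname(f["spike_width_ms"]) - 0.4), 0.05)

  f2 <- waveform_features(2 * m, fs = fs)
  expect_equal(unname(f2[1:2]), 2 * unname(f[1:2]))
  expect_equal(f2["spike_width_ms"], f["spike_width_ms"])

  # pure negative lobe: no positive peak, width undefined
  f3 <- waveform_features(cbind(-80 * exp(-(t_ms - 0.5)^2 / 0.02)), fs = fs)
  expect_true(is.na(f3["spike_width_ms"]))
})
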