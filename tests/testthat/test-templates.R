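# Build a spike_clips object directly from an n x L x N array.
clips_from_array <- function(w, fs = 31250) {
  structure(list(waves = w, times = seq_len(dim(w)[1]) * 0.01,
                 start_samples = seq_len(dim(w)[1]) * 300,
                 fs = fs, L = dim(w)[2], pre_samples = 16L,
                 channels = seq_len(dim(w)[3]), aligned = TRUE),
            class = "spike_clips")
}

test_that("a template is the channel-major mean of its clips", {
  set.seed(31)
  w <- array(rnorm(2 * 47 * 4), c(2, 47, 4))
  cl <- clips_from_array(w)

  # single clip: template equals the clip flattened channel-major
  tp <- compute_template(cl, c(1L, 2L), 1L)
  expect_equal(tp$mu, as.vector(w[1, , ]))
  expect_equal(length(tp$mu), 47 * 4)
  expect_equal(tp$mu[1:47], w[1, , 1])     # channel 1 block first

  # x and -x average to a degenerate all-zero template
  w2 <- array(0, c(2, 47, 4))
  w2[1, , ] <- w[1, , ]; w2[2, , ] <- -w[1, , ]
  expect_error(compute_template(clips_from_array(w2), c(1L, 1L), 1L),
               "degenerate template")
  expect_error(compute_template(cl, c(1L, 2L), 9L), "no clips")

  # mean of noisy copies concentrates on the underlying waveform
  base <- array(rnorm(47 * 4), c(47, 4))
  n <- 100
  w3 <- array(rnorm(n * 47 * 4, sd = 0.5), c(n, 47, 4)) +
    aperm(array(base, c(47, 4, n)), c(3, 1, 2))
  tp3 <- compute_template(clips_from_array(w3), rep(1L, n), 1L)
  expect_lt(max(abs(tp3$mu_mat - base)), 5 * 0.5 / sqrt(n))
  expect_equal(tp3$n_spikes_used, n)
})

test_that("clip assignment picks the most similar template with a floor", {
  set.seed(32)
  t1 <- array(rnorm(47 * 4), c(47, 4))
  t2 <- array(rnorm(47 * 4), c(47, 4))
  tmps <- list(make_template(t1, unit_id = 1L),
               make_template(t2, unit_id = 2L))
  w <- array(0, c(3, 47, 4))
  w[1, , ] <- t2                            # exact copy of template 2
  w[2, , ] <- rnorm(47 * 4)                 # unrelated noise
  w[3, , ] <- t1
  cl <- clips_from_array(w)
  labels <- assign_clips(cl, tmps)
  expect_equal(labels[1], 2L)
  expect_equal(labels[3], 1L)
  # noise clip: verify the rejection against brute-force similarities
  sims <- vapply(tmps, function(tp) clip_similarity(w[2, , ], tp), 0)
  expect_true(all(sims < 0.7))
  expect_equal(labels[2], -1L)

  # exact tie between identical templates -> lower unit id
  tie <- assign_clips(cl, list(make_template(t1, unit_id = 4L),
                               make_template(t1, unit_id = 3L)))
  expect_equal(tie[3], 3L)
})

test_that("templates reproduce their own training clips above the floor", {
  set.seed(33)
  base <- array(rnorm(47 * 4, sd = 30), c(47, 4))
  n <- 40
  w <- aperm(array(base, c(47, 4, n)), c(3, 1, 2)) +
    array(rnorm(n * 47 * 4, sd = 5), c(n, 47, 4))
  cl <- clips_from_array(w)
  tp <- compute_template(cl, rep(1L, n), 1L)
  expect_true(all(assign_clips(cl, list(tp)) == 1L))
})

test_that("refractory violation fraction counts short ISIs over all spikes", {
  expect_equal(refractory_violation_frac(c(0, 0.010, 0.020)), 0)
  expect_equal(refractory_violation_frac(c(0, 0.001, 0.010)), 1 / 3)
  expect_equal(refractory_violation_frac(numeric(0)), 0)
  expect_equal(refractory_violation_frac(0.5), 0)
  expect_equal(refractory_violation_frac(c(0, 0.0014, 0.0016, 0.01)), 2 / 4)
})

test_that("missing-spike estimate matches closed forms", {
  set.seed(34)
  # amplitudes centred exactly at threshold -> half the mass is missed
  amps <- -70 + rnorm(4000, 0, 10)
  m <- estimate_missing_frac(amps, -70)
  expect_lt(abs(m - 0.5), 0.03)

  # complete N(-80, 10) sample, threshold -70 -> Phi(-1)
  amps2 <- rnorm(4000, -80, 10)
  m2 <- estimate_missing_frac(amps2, -70)
  expect_lt(abs(m2 - pnorm(-1)), 0.02)

  # everything far below threshold -> essentially nothing missed
  amps3 <- rnorm(1000, -200, 5)
  expect_lt(estimate_missing_frac(amps3, -70), 1e-6)

  # monotone non-decreasing as the threshold approaches the fitted mean
  ths <- c(-80, -85, -90, -95)
  ms <- vapply(ths, function(th)
    estimate_missing_frac(amps2[amps2 <= -95], th, method = "moment"), 0)
  expect_true(all(diff(ms) >= 0))

  expect_error(estimate_missing_frac(rnorm(5, -80), -70), "at least 10")
  expect_error(estimate_missing_frac(rnorm(20, -80, 5), 70), "negative")
})

test_that("Mahalanobis distance matches closed forms", {
  set.seed(35)
  # 2-feature toy with diagonal covariance diag(4, 1)
  X <- cbind(rnorm(4000, 0, 2), rnorm(4000, 0, 1))
  X <- sweep(X, 2, colMeans(X))            # exact zero mean
  d <- mahalanobis_to_cluster(colMeans(X) + c(2, 1), X, reduce = FALSE)
  expect_equal(d, sqrt(2), tolerance = 0.05)

  # clip at the cluster mean -> zero
  expect_equal(mahalanobis_to_cluster(colMeans(X), X, reduce = FALSE), 0)

  # identity covariance -> Euclidean distance
  Z <- matrix(rnorm(8000), ncol = 2)
  Z <- sweep(Z, 2, colMeans(Z))
  S <- cov(Z)
  Zw <- Z %*% solve(chol(S))               # whitened: covariance == identity
  v <- c(1.2, -0.7)
  expect_equal(mahalanobis_to_cluster(v, Zw, reduce = FALSE),
               sqrt(sum((v - colMeans(Zw))^2)), tolerance = 1e-6)

  # waveform path: distance of a cluster member is finite and small
  base <- array(rnorm(47 * 4, sd = 30), c(47, 4))
  n <- 60
  w <- aperm(array(base, c(47, 4, n)), c(3, 1, 2)) +
    array(rnorm(n * 47 * 4, sd = 5), c(n, 47, 4))
  d2 <- mahalanobis_to_cluster(w[1, , ], w, n_pc = 3)
  expect_true(is.finite(d2) && d2 >= 0)

  # singular covariance is reported, not silently inverted
  dup <- cbind(Z[, 1], Z[, 1])
  expect_error(mahalanobis_to_cluster(c(0, 0), dup, reduce = FALSE),
               "singular")
})

test_that("the single-unit gate applies the two printed cut-offs", {
  set.seed(36)
  good_t <- seq(0, 10, by = 0.05)
  good_a <- rnorm(300, -90, 8)
  q <- quality_report(good_t, good_a, -40)
  expect_true(q$passes_single_unit)

  bad_rv <- quality_report(c(good_t, good_t + 0.0005), good_a, -40)
  expect_false(bad_rv$passes_single_unit)

  bad_mf <- quality_report(good_t, rnorm(300, -41, 10), -40)
  expect_gt(bad_mf$missing_frac_estimate, 0.30)
  expect_false(bad_mf$passes_single_unit)
})
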