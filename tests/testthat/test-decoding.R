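# Deterministic two-class tensor: class-1 trials elevate the first
# `n_resp` neurons inside [0, 5); pure noise elsewhere.
make_tensor <- function(n_neurons = 20, n_resp = 8, m_per_class = 12,
                        sep = 2, noise = 0.3, seed = 50, fs = 10) {
  set.seed(seed)
  n_fr <- 100
  tt <- (seq_len(n_fr) - 1 - 50) / fs
  mk_ep <- function(active) {
    x <- array(rnorm(n_neurons * m_per_class * n_fr, sd = noise),
               dim = c(n_neurons, m_per_class, n_fr),
               dimnames = list(paste0("n", 1:n_neurons), NULL, NULL))
    if (active) {
      x[1:n_resp, , tt >= 0 & tt < 5] <- x[1:n_resp, , tt >= 0 & tt < 5] + sep
    }
    structure(x, pre_s = 5, post_s = 5, frame_rate = fs, align_index = 50L,
              trial_event_ids = 1:m_per_class, n_excluded = 0L,
              label = if (active) "A" else "B",
              neuron_ids = paste0("n", 1:n_neurons), stage = "zscored",
              class = c("epoch_tensor", "array"))
  }
  list(a = mk_ep(TRUE), b = mk_ep(FALSE))
}

test_that("trial tensors stack trials with binary labels", {
  eps <- make_tensor(m_per_class = 10)
  epb <- make_tensor(m_per_class = 12)$b
  tens <- build_trial_tensor(eps$a, epb, paste0("n", 1:20))
  expect_equal(dim(tens$activity), c(20, 22, 100))
  expect_equal(sum(tens$labels), 10)

  expect_error(build_trial_tensor(eps$a, eps$b, character(0)), "non-empty")
  expect_error(build_trial_tensor(eps$a, eps$b, c("n1", "zz")), "alignment")
  short <- eps$b
  attr(short, "pre_s") <- 4
  expect_error(build_trial_tensor(eps$a, short, "n1"), "alignment")
})

test_that("cross-validated decoding separates separable classes and handles folds", {
  eps <- make_tensor(sep = 3)
  tens <- build_trial_tensor(eps$a, eps$b, paste0("n", 1:20))
  out <- decode_cv(tens, folds = 10, seed = 1)
  expect_equal(out$mean_accuracy, 1.0)
  expect_length(out$fold_accuracies, 10)
  expect_length(out$weights, 20)

  # hyperplane orientation: class A (label 1) on the positive side
  feats <- sapply(seq_len(dim(tens$activity)[2]), function(m) {
    rowMeans(tens$activity[, m, 51:100])
  })
  std <- sweep(sweep(t(feats), 2, colMeans(t(feats)), "-"), 2,
               apply(t(feats), 2, sd), "/")
  dv <- drop(std %*% out$weights) + out$intercept
  expect_gt(mean(dv[tens$labels == 1]), mean(dv[tens$labels == 0]))

  small <- make_tensor(m_per_class = 3)
  tens_s <- build_trial_tensor(small$a, small$b, paste0("n", 1:20))
  expect_warning(out_s <- decode_cv(tens_s, folds = 10, seed = 1),
                 "reducing folds to 3")
  expect_equal(out_s$folds, 3)

  one_class <- tens
  one_class$labels <- rep(1L, length(tens$labels))
  expect_error(decode_cv(one_class, seed = 1), "label error")
})

test_that("decoder accuracy is invariant to a common affine feature rescale", {
  eps <- make_tensor(sep = 0.8, seed = 51)
  tens <- build_trial_tensor(eps$a, eps$b, paste0("n", 1:20))
  tens2 <- tens
  tens2$activity <- tens$activity * 17 - 4
  a1 <- decode_cv(tens, folds = 5, seed = 3)
  a2 <- decode_cv(tens2, folds = 5, seed = 3)
  expect_equal(a1$fold_accuracies, a2$fold_accuracies)
})

test_that("shuffled-label nulls sit at chance and bound the real accuracy", {
  eps <- make_tensor(sep = 3)
  tens <- build_trial_tensor(eps$a, eps$b, paste0("n", 1:20))
  nl <- shuffled_null(tens, n_shuffles = 25, folds = 5, seed = 2)
  expect_equal(nl$real$mean_accuracy, 1.0)
  expect_true(all(nl$null_accuracies < 1.0))
  expect_equal(nl$p_value, 1 / 26)
  # chance calibration of the null distribution
  expect_lt(abs(mean(nl$null_accuracies) - 0.5),
            1.96 * sqrt(0.25 / length(tens$labels)))
  expect_error(shuffled_null(tens, n_shuffles = 0), "n_shuffles")
})

test_that("performance CDFs are valid empirical distributions", {
  one <- performance_cdf(rep(1, 10))
  expect_equal(one, data.frame(accuracy = 1, cum_prob = 1))
  two <- performance_cdf(c(0.5, 1))
  expect_equal(two$cum_prob, c(0.5, 1))
  set.seed(52)
  any_cdf <- performance_cdf(runif(30))
  expect_true(all(diff(any_cdf$cum_prob) > 0))
  expect_equal(any_cdf$cum_prob[nrow(any_cdf)], 1)
  expect_error(performance_cdf(numeric(0)), "empty")
})

test_that("decoding time courses track when class information appears", {
  eps <- make_tensor(n_neurons = 16, n_resp = 8, m_per_class = 15, sep = 2.5,
                     seed = 53)
  tc <- decode_timecourse(eps$a, eps$b, paste0("n", 1:16),
                          time_grid = c(-4, -2.5, 1, 2.5), folds = 5,
                          n_shuffles = 4, seed = 6)
  expect_lt(max(tc$accuracy[1:2]), 0.75)   # pre-onset: no information
  expect_gt(min(tc$accuracy[3:4]), 0.9)    # post-onset: strong information
  expect_true(all(abs(tc$null_accuracy - 0.5) < 0.25))
  expect_error(decode_timecourse(eps$a, eps$b, paste0("n", 1:16),
                                 time_grid = c(0, 6)), "window error")
})

test_that("event agreement metrics follow interval arithmetic", {
  iv <- function(s, e) data.frame(start_s = s, end_s = e)
  same <- event_agreement(iv(c(1, 5), c(2, 7)), iv(c(1, 5), c(2, 7)),
                          span = c(0, 10), frame_rate = 100)
  expect_equal(same$accuracy, 1.0)
  expect_equal(same$iou, 1.0)
  expect_equal(same$hit_rate, 1.0)

  disj <- event_agreement(iv(1, 2), iv(5, 6), span = c(0, 10), frame_rate = 100)
  expect_equal(disj$iou, 0)

  half <- event_agreement(iv(0, 2), iv(1, 3), span = c(0, 4), frame_rate = 1000)
  expect_equal(half$iou, 1 / 3, tolerance = 1e-2)

  expect_warning(none <- event_agreement(iv(1, 2), iv(numeric(0), numeric(0)),
                                         span = c(0, 10), frame_rate = 100),
                 "hit rate")
  expect_true(is.na(none$hit_rate))
})

test_that("projection decoding is positive during events and obeys thresholds", {
  s <- generate_session(one_event_config(seed = 61, amplitude = 4,
                                         n_neurons = 80, fraction = 0.25,
                                         n_trials = 16, duration_s = 800,
                                         window = c(0, 6), event_duration = 6,
                                         jitter_sd = 0))
  z <- process_session(s)
  sub <- gt_members(s, "A")
  pr <- projection_decoder(z, s$events, "A", sub)
  ev <- s$events[s$events$label == "A" & s$events$onset_s > pr$test_span[1], ]
  in_event <- vapply(pr$projection$time_s, function(t) {
    any(t >= ev$onset_s & t < ev$offset_s)
  }, logical(1))
  expect_gt(mean(pr$projection$distance[in_event]),
            mean(pr$projection$distance[!in_event]))
  expect_true(all(pr$predicted_intervals$start_s >= pr$test_span[1]))
  expect_true(all(diff(as.vector(t(pr$predicted_intervals))) >= 0))

  none <- projection_decoder(z, s$events, "A", sub, threshold = Inf)
  expect_equal(nrow(none$predicted_intervals), 0)

  expect_error(projection_decoder(z, s$events, "A", character(0)), "non-empty")
  late <- event_table("A", 700, 706)
  expect_error(projection_decoder(z, late, "A", sub), "split error")
})

test_that("removing responsive neurons never raises expected accuracy", {
  accs <- vapply(c(0, 4, 8), function(n_zero) {
    mean(vapply(1:3, function(k) {
      eps <- make_tensor(n_neurons = 16, n_resp = 8, sep = 1, seed = 90 + k)
      tens <- build_trial_tensor(eps$a, eps$b, paste0("n", 1:16))
      if (n_zero > 0) tens$activity[seq_len(n_zero), , ] <- 0
      decode_cv(tens, folds = 5, seed = k)$mean_accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.05))
  expect_lt(accs[3], accs[1])
})
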