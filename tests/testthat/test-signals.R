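test_that("compute_dff applies (F - F0)/F0 with a session or windowed baseline", {
  fs <- 10
  f0 <- c(2, 5)
  tm <- trace_matrix(rbind(rep(2, 40), rep(5, 40)), fs)
  expect_equal(as.vector(unclass(compute_dff(tm))), rep(0, 80))

  tm2 <- trace_matrix(rbind(rep(4, 40), rep(10, 40)), fs)
  # F is constant so session F0 = F; use a doubled second half instead
  raw <- rbind(c(rep(2, 20), rep(4, 20)), c(rep(5, 20), rep(10, 20)))
  dff <- compute_dff(trace_matrix(raw, fs), f0_window = c(0, 2))
  expect_equal(unname(unclass(dff)[, 1]), c(0, 0))
  expect_equal(unname(unclass(dff)[, 40]), c(1, 1))
  expect_identical(trace_stage(dff), "dff")

  # direct arithmetic: raw [1,1,1,3], F0 from the first 3 samples
  d <- compute_dff(trace_matrix(c(1, 1, 1, 3), frame_rate = 1),
                   f0_window = c(0, 3))
  expect_equal(as.numeric(d), c(0, 0, 0, 2))
})

test_that("compute_dff is invariant to positive rescaling of the raw signal", {
  set.seed(1)
  raw <- matrix(abs(rnorm(200, 10)), 4)
  a <- compute_dff(trace_matrix(raw, 20))
  b <- compute_dff(trace_matrix(3.7 * raw, 20))
  expect_equal(as.vector(unclass(a)), as.vector(unclass(b)), tolerance = 1e-12)
})

test_that("compute_dff rejects nonpositive baselines, naming the neuron", {
  raw <- rbind(rep(1, 10), rep(-2, 10))
  tm <- trace_matrix(raw, 10, neuron_ids = c("good", "bad"))
  expect_error(compute_dff(tm), "degenerate baseline.*bad")
})

test_that("z-scoring uses the population SD and excludes constant neurons", {
  z <- zscore_traces(trace_matrix(c(0, 2), frame_rate = 1, stage = "dff"))
  expect_equal(as.numeric(z), c(-1, 1))  # divide-by-n convention
  expect_identical(trace_stage(z), "zscored")

  set.seed(2)
  x <- rnorm(1000)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  z2 <- zscore_traces(trace_matrix(x, 30, stage = "dff"))
  expect_equal(as.numeric(z2), x, tolerance = 1e-9)

  tm <- trace_matrix(rbind(rnorm(50), rep(3, 50)), 10,
                     neuron_ids = c("a", "flat"), stage = "dff")
  expect_warning(z3 <- zscore_traces(tm), "flat")
  expect_identical(attr(z3, "excluded"), "flat")
  expect_equal(nrow(z3), 1L)
  # invariant: per-neuron mean ~ 0, SD ~ 1
  expect_lt(abs(mean(z3)), 1e-10)
  expect_lt(abs(sqrt(mean((z3 - mean(z3))^2)) - 1), 1e-10)
})

test_that("epoch extraction yields the stated frame counts and alignment", {
  set.seed(3)
  tm <- trace_matrix(matrix(rnorm(2 * 30 * 120), 2), 30, stage = "zscored")
  ev <- event_table(c("A", "A", "A"), c(2, 40, 80))
  expect_warning(ep <- extract_epochs(tm, ev, "A"), NA)
  # 10 s pre + 10 s post at 30 FPS = 600 frames; onset at 0-based frame 300
  expect_equal(dim(ep)[3], 600L)
  expect_equal(attr(ep, "align_index"), 300L)
  # the event at t = 2 s cannot supply 10 s of pre-onset data
  expect_equal(attr(ep, "n_excluded"), 1L)
  expect_equal(dim(ep)[2], 2L)

  tm100 <- trace_matrix(matrix(rnorm(100 * 60), 1), 100, stage = "dff")
  ep100 <- extract_epochs(tm100, event_table("b", 30), "b")
  expect_equal(dim(ep100)[3], 2000L)  # 20 s x 100 Hz
})

test_that("epoch slices reproduce the session samples at aligned indices", {
  set.seed(4)
  tm <- trace_matrix(matrix(rnorm(3 * 600), 3), 20, stage = "zscored")
  ev <- event_table("A", c(12.3, 25.0))
  ep <- extract_epochs(tm, ev, "A", pre_s = 5, post_s = 5)
  for (k in seq_len(2)) {
    onset_frame <- floor(ev$onset_s[k] * 20) + 1
    expect_identical(ep[, k, ],
                     unclass(tm)[, (onset_frame - 100):(onset_frame + 99)])
  }
  expect_error(extract_epochs(tm, event_table("A", 1), "A", pre_s = 5),
               "no usable trials")
  expect_error(extract_epochs(tm, ev, "missing"), "no events")
})

test_that("window_stat computes mean, max and AUC over half-open windows", {
  ep <- toy_epochs(matrix(2, nrow = 3, ncol = 100), frame_rate = 10)
  expect_equal(window_stat(ep, c(0, 5), "mean"), matrix(2, 1, 3,
               dimnames = list("n1", NULL)))
  # constant c over a 5-s window integrates to exactly 5c
  expect_equal(unname(window_stat(ep, c(-2, 3), "auc")), matrix(10, 1, 3))

  # single-peak max against a brute-force scan
  set.seed(5)
  vals <- matrix(rnorm(4 * 100), 4, 100)
  ep2 <- toy_epochs(vals, frame_rate = 10)
  got <- window_stat(ep2, c(-2, 3), "max")
  tt <- (seq_len(100) - 1 - 50) / 10
  manual <- apply(vals[, tt >= -2 & tt < 3, drop = FALSE], 1, max)
  expect_equal(unname(got[1, ]), manual)

  expect_error(window_stat(ep, c(40, 50), "mean"), "outside the epoch")
})

test_that("full-epoch windowed mean equals the plain per-trial mean", {
  set.seed(6)
  vals <- matrix(rnorm(6 * 100), 6, 100)
  ep <- toy_epochs(vals, frame_rate = 10)
  expect_equal(unname(window_stat(ep, c(-5, 5), "mean")[1, ]),
               rowMeans(vals))
})

test_that("onset latency finds the first crossing of the 2-SD band", {
  set.seed(7)
  base <- rnorm(200)
  series <- c(base, rep(mean(base), 49), 10, rep(10, 50))
  tt <- seq_along(series) / 10 - 20.1  # baseline spans [-20, 0)
  lat <- onset_latency(series, times = tt, baseline = window_spec(-20, 0))
  expect_equal(lat, tt[250])  # the step sample

  flat <- onset_latency(rep(c(0, 1), 50), times = seq(0.1, 10, 0.1),
                        baseline = window_spec(0, 5))
  expect_true(is.na(flat))

  neg <- c(base, rep(mean(base), 49), -10, rep(-10, 20))
  lat_dn <- onset_latency(neg, times = seq_along(neg) / 10 - 20.1,
                          baseline = window_spec(-20, 0), direction = "below")
  expect_equal(lat_dn, tt[250])

  expect_error(onset_latency(c(rep(1, 50), 5), times = 1:51,
                             baseline = window_spec(1, 50)),
               "degenerate baseline")
})
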