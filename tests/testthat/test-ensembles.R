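test_that("permutation p-values match exhaustive enumeration on toy inputs", {
  set.seed(31)
  for (n_tr in c(4, 6, 8)) {
    vals <- lapply(1:3, function(i) matrix(rnorm(n_tr * 100, sd = 1), n_tr, 100))
    vals[[1]][, 51:100] <- vals[[1]][, 51:100] + 1.2  # one responsive neuron
    ep <- toy_epochs(vals, frame_rate = 10)
    res <- detect_activated(ep, exact = TRUE)
    expect_equal(res$p_value, oracle_exact_p(ep), tolerance = 0)
  }
})

test_that("activation is conjunctive: both the test and the 0.2 z rule bind", {
  set.seed(32)
  n_tr <- 20
  mk <- function(shift) {
    m <- matrix(rnorm(n_tr * 100, sd = 0.05), n_tr, 100)
    m[, 51:100] <- m[, 51:100] + shift
    m
  }
  # strong response: permutation floor p and mean 1.5 z -> activated
  # significant but tiny response (0.1 z) -> NOT activated
  ep <- toy_epochs(list(mk(1.5), mk(0.1), mk(0)), frame_rate = 10)
  res <- detect_activated(ep, n_perm = 999, seed = 1)
  expect_true(res$activated[1])
  expect_equal(res$p_value[1], 1 / 1000)      # the +1-smoothed floor
  expect_lt(res$p_value[2], 0.05)             # significant ...
  expect_false(res$activated[2])              # ... but below the 0.2 z rule
  expect_false(res$activated[3])
  expect_true(all(res$p_value >= 1 / 1000 & res$p_value <= 1))
})

test_that("detect_activated validates windows and trial counts", {
  ep <- toy_epochs(matrix(rnorm(200), 2, 100), frame_rate = 10)
  expect_error(detect_activated(ep, baseline = c(-5, 1), event = c(0, 5)),
               "overlap")
  ep1 <- toy_epochs(matrix(rnorm(100), 1, 100), frame_rate = 10)
  expect_error(detect_activated(ep1), "2 trials")
  expect_identical(detect_activated(ep, seed = 5)$p_value,
                   detect_activated(ep, seed = 5)$p_value)
})

test_that("SRI follows (A-B)/(A+B) with a guarded denominator", {
  expect_equal(unname(compute_sri(0.3, 0.1)), 0.5)
  expect_equal(unname(compute_sri(0.4, 0.4)), 0)
  expect_true(is.na(compute_sri(0.2, -0.2)))
  expect_true(is.na(compute_sri(-0.1, -0.3)))

  # antisymmetry wherever defined
  set.seed(33)
  A <- runif(50); B <- runif(50)
  s_ab <- compute_sri(A, B); s_ba <- compute_sri(B, A)
  expect_equal(s_ab, -s_ba)
  expect_true(all(abs(s_ab) <= 1, na.rm = TRUE))

  # joins on names, not position
  a <- c(x = 0.3, y = 0.1); b <- c(y = 0.1, x = 0.1)
  expect_equal(unname(compute_sri(a, b)["x"]), 0.5)
  expect_error(compute_sri(c(x = 1), c(z = 1)), "registration")
})

test_that("selectivity categories follow the +/-0.2 cut-offs", {
  got <- classify_selectivity(c(0.25, -0.30, 0, 0.2, -0.2, NA))
  expect_equal(as.character(got),
               c("A_selective", "B_selective", "shared", "shared", "shared",
                 "undefined"))
})

test_that("phase phenotyping separates pre- and post-onset responders", {
  set.seed(34)
  n_tr <- 15; n_fr <- 200; fs <- 10  # epoch [-10, +10] s
  tt <- (seq_len(n_fr) - 1 - 100) / fs
  mk <- function(lo, hi, amp) {
    m <- matrix(rnorm(n_tr * n_fr, sd = 0.05), n_tr, n_fr)
    m[, tt >= lo & tt < hi] <- m[, tt >= lo & tt < hi] + amp
    m
  }
  ep <- toy_epochs(list(mk(-4, -1, 1.5),   # ramps before onset only
                        mk(1, 4, 1.5),     # responds after onset only
                        mk(0, 0, 0)),      # flat
                   frame_rate = fs, pre_s = 10, post_s = 10)
  res <- identify_phase_cells(ep, seed = 2)
  expect_equal(as.character(res$phase), c("pre", "post", "neither"))
  expect_gt(res$max_response_pre[1], 0.2)
  expect_gt(res$max_response_post[2], 0.2)
})

test_that("detection sensitivity rises with response amplitude", {
  sens <- vapply(c(0.2, 1, 2.5), function(amp) {
    s <- generate_session(one_event_config(seed = 40, amplitude = amp,
                                           n_neurons = 60, fraction = 0.3,
                                           duration_s = 560))
    z <- process_session(s)
    ep <- extract_epochs(z, s$events, "A")
    res <- detect_activated(ep, n_perm = 500, seed = 4)
    mean(res$activated[res$neuron %in% gt_members(s, "A")])
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], sens[1])
})

test_that("registered joins keep matched neurons and report the rest", {
  ra <- data.frame(neuron = paste0("a", 1:100), p_value = runif(100))
  rb <- data.frame(neuron = paste0("b", 1:100), p_value = runif(100))
  ident <- data.frame(id_a = ra$neuron, id_b = rb$neuron)
  full <- join_registered(ra, rb, ident)
  expect_equal(nrow(full$matched), 100)
  expect_length(full$unmatched_a, 0)

  none <- join_registered(ra, rb, data.frame(id_a = character(0),
                                             id_b = character(0)))
  expect_equal(nrow(none$matched), 0)
  expect_length(none$unmatched_a, 100)
  expect_length(none$unmatched_b, 100)

  part <- join_registered(ra, rb, ident[1:10, ])
  expect_equal(nrow(part$matched), 10)
  expect_length(part$unmatched_a, 90)
  expect_length(part$unmatched_b, 90)

  expect_error(join_registered(ra, rb,
                               data.frame(id_a = c("a1", "a1"),
                                          id_b = c("b1", "b2"))),
               "duplicate")
})
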