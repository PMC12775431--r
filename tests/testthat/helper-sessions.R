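# Shared fixture builders. All sessions are generated in code at test time;
# sizes are kept small where the property under test allows it.

# One-event session: `fraction` of neurons respond to label "A" with the given
# amplitude in a 2-s window after onset.
one_event_config <- function(seed, amplitude, n_neurons = 100,
                             n_trials = 20, duration_s = 560,
                             window = c(0, 2), event_duration = 2,
                             jitter_sd = 0.1, fraction = 0.15, ...) {
  session_config(
    n_neurons = n_neurons, duration_s = duration_s, seed = seed,
    ensembles = list(list(event = "A", fraction = fraction,
                          amplitude = amplitude, window = window,
                          jitter_sd = jitter_sd)),
    event_schedule = list(list(label = "A", n_trials = n_trials,
                               min_spacing = 21, duration = event_duration)),
    ...)
}

# Two-event session with (nominally) disjoint ensembles on a shared timeline.
two_event_config <- function(seed, amplitude, n_neurons = 150,
                             n_trials = 20, duration_s = 1000,
                             fraction = 0.2) {
  mk_ens <- function(ev) list(event = ev, fraction = fraction,
                              amplitude = amplitude, window = c(0, 2),
                              jitter_sd = 0.1)
  mk_sched <- function(ev) list(label = ev, n_trials = n_trials,
                                min_spacing = 21, duration = 2)
  session_config(n_neurons = n_neurons, duration_s = duration_s, seed = seed,
                 ensembles = list(mk_ens("A"), mk_ens("B")),
                 event_schedule = list(mk_sched("A"), mk_sched("B")))
}

# Ground-truth member ids for one event label.
gt_members <- function(session, label) {
  names(Filter(function(v) label %in% v, session$ground_truth$responsive_map))
}

# Standard processing: raw -> dff -> z-score.
process_session <- function(session) {
  zscore_traces(compute_dff(session$traces))
}

# Build an epoch tensor directly from a trials x frames matrix replicated (or
# supplied) per neuron; used for hand-constructed toy inputs.
toy_epochs <- function(values, frame_rate = 10, pre_s = 5, post_s = 5) {
  # values: list of neuron matrices (trials x frames) or one matrix
  if (is.matrix(values)) values <- list(values)
  n_frames <- ncol(values[[1]])
  stopifnot(n_frames == round((pre_s + post_s) * frame_rate))
  x <- array(NA_real_, dim = c(length(values), nrow(values[[1]]), n_frames),
             dimnames = list(paste0("n", seq_along(values)), NULL, NULL))
  for (i in seq_along(values)) x[i, , ] <- values[[i]]
  structure(x,
            pre_s = pre_s, post_s = post_s, frame_rate = frame_rate,
            align_index = as.integer(round(pre_s * frame_rate)),
            trial_event_ids = seq_len(nrow(values[[1]])),
            n_excluded = 0L, label = "toy",
            neuron_ids = paste0("n", seq_along(values)), stage = "zscored",
            class = c("epoch_tensor", "array"))
}

# Independent brute-force enumeration of the within-trial window-exchange
# permutation test (the oracle for the exact p-value). Recomputes everything
# from the epoch array with plain loops.
oracle_exact_p <- function(epochs, baseline = c(-5, 0), event = c(0, 5),
                           statistic = "mean") {
  fs <- attr(epochs, "frame_rate")
  align <- attr(epochs, "align_index")
  tt <- (seq_len(dim(epochs)[3]) - 1 - align) / fs
  in_b <- which(tt >= baseline[1] & tt < baseline[2])
  in_e <- which(tt >= event[1] & tt < event[2])
  red <- if (statistic == "mean") mean else max
  n_tr <- dim(epochs)[2]
  vapply(seq_len(dim(epochs)[1]), function(i) {
    d <- numeric(n_tr)
    for (m in seq_len(n_tr)) {
      d[m] <- red(epochs[i, m, in_e]) - red(epochs[i, m, in_b])
    }
    obs <- mean(d)
    count <- 0L
    for (mask in 0:(2^n_tr - 1)) {
      signs <- ifelse(bitwAnd(mask, 2^(seq_len(n_tr) - 1)) > 0, -1, 1)
      if (mean(signs * d) >= obs - 1e-12) count <- count + 1L
    }
    count / 2^n_tr
  }, numeric(1))
}
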