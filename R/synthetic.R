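#' Configure a synthetic imaging session
#'
#' Describes a miniscope-like recording with designated event-responsive
#' subpopulations. Every trace is built as
#' `baseline_f0 + drift + transients + Gaussian noise`, where transients are
#' per-frame Bernoulli "spikes" convolved with a difference-of-exponentials
#' calcium kernel normalized to unit peak. Responsive neurons receive extra
#' spikes inside their ensemble's response window on each trial of the
#' ensemble's event; their spike amplitude is calibrated analytically so that
#' `response_amplitude` is (approximately) the mean z-scored elevation over
#' the standard 5-s analysis window. Non-responsive neurons carry identical
#' background statistics with no event-locked term.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param frame_rate Sampling rate in Hz (default 30, miniscope-like).
#' @param duration_s Session length in seconds.
#' @param seed Master seed; all randomness derives from it through per-neuron
#'   child seeds, so adding neurons never changes earlier neurons' traces.
#' @param ensembles List of ensembles, each a list with `event` (label),
#'   `fraction` (member fraction of the population, in \[0, 1\]),
#'   `amplitude` (target response in z units), `window` (`c(t0, t1)` seconds
#'   relative to onset in which response spikes occur), and `jitter_sd`
#'   (onset jitter SD in seconds).
#' @param event_schedule List of schedules, each a list with `label`,
#'   `n_trials`, `min_spacing` (s, must exceed twice `epoch_half_s` so epochs
#'   never truncate by construction), and `duration` (s).
#' @param kernel List with `rise_tau`, `decay_tau` (s, both > 0; defaults
#'   0.2 / 1.5, GCaMP6s-like).
#' @param noise_sd Gaussian noise SD in fluorescence units.
#' @param drift_amplitude Amplitude of the slow drift (sinusoid + random walk)
#'   in fluorescence units; default 5% of `baseline_f0`.
#' @param baseline_f0 Baseline fluorescence level (> 0).
#' @param baseline_spike_rate Background transient rate for every neuron, in
#'   spikes per frame (default 0.01).
#' @param epoch_half_s Half-width of the downstream peri-event epoch (default
#'   10 s); used only to validate `min_spacing`.
#' @param disjoint_ensembles If `TRUE` (default) neurons belong to at most one
#'   ensemble (one membership uniform per neuron partitioned by cumulative
#'   fractions, which must then sum to <= 1); `FALSE` draws memberships
#'   independently, allowing overlap.
#' @param shared_timeline If `TRUE` (default) all event labels share one
#'   behavioral timeline: onsets are drawn jointly with the largest requested
#'   `min_spacing` between any two events, so events of different labels never
#'   coincide (a mouse is not in two events at once) and peri-event epochs are
#'   unconfounded. `FALSE` draws each label's schedule independently, which
#'   permits cross-label collisions.
#' @return A validated `session_config` list.
#' @export
session_config <- function(n_neurons = 200, frame_rate = 30, duration_s = 600,
                           seed = 1,
                           ensembles = list(),
                           event_schedule = list(),
                           kernel = list(rise_tau = 0.2, decay_tau = 1.5),
                           noise_sd = 10, drift_amplitude = 0.05 * baseline_f0,
                           baseline_f0 = 100, baseline_spike_rate = 0.01,
                           epoch_half_s = 10, shared_timeline = TRUE,
                           disjoint_ensembles = TRUE) {
  fail <- function(field, msg) stop("invalid config: `", field, "` ", msg)
  if (!is.numeric(n_neurons) || n_neurons < 1) fail("n_neurons", "must be >= 1")
  if (!is.numeric(frame_rate) || frame_rate <= 0) fail("frame_rate", "must be > 0")
  if (!is.numeric(duration_s) || duration_s <= 0) fail("duration_s", "must be > 0")
  if (!is.numeric(seed) || length(seed) != 1) fail("seed", "must be one integer")
  if (!is.numeric(kernel$rise_tau) || kernel$rise_tau <= 0) fail("kernel$rise_tau", "must be > 0")
  if (!is.numeric(kernel$decay_tau) || kernel$decay_tau <= 0) fail("kernel$decay_tau", "must be > 0")
  if (kernel$decay_tau <= kernel$rise_tau) fail("kernel$decay_tau", "must exceed rise_tau")
  if (!is.numeric(noise_sd) || noise_sd <= 0) fail("noise_sd", "must be > 0")
  if (!is.numeric(baseline_f0) || baseline_f0 <= 0) fail("baseline_f0", "must be > 0")
  if (drift_amplitude < 0) fail("drift_amplitude", "must be >= 0")
  if (baseline_spike_rate < 0 || baseline_spike_rate >= 1) {
    fail("baseline_spike_rate", "must be in [0, 1) per frame")
  }
  for (i in seq_along(ensembles)) {
    en <- ensembles[[i]]
    if (is.null(en$event)) fail(paste0("ensembles[[", i, "]]$event"), "is required")
    if (is.null(en$fraction) || en$fraction < 0 || en$fraction > 1) {
      fail(paste0("ensembles[[", i, "]]$fraction"), "must be in [0, 1]")
    }
    if (is.null(en$amplitude) || en$amplitude < 0) {
      fail(paste0("ensembles[[", i, "]]$amplitude"), "must be >= 0 (z units)")
    }
    if (is.null(en$window) || length(en$window) != 2 || en$window[1] >= en$window[2]) {
      fail(paste0("ensembles[[", i, "]]$window"), "must be c(t0, t1) with t0 < t1")
    }
    if (is.null(en$jitter_sd)) ensembles[[i]]$jitter_sd <- 0
    else if (en$jitter_sd < 0) fail(paste0("ensembles[[", i, "]]$jitter_sd"), "must be >= 0")
  }
  if (isTRUE(disjoint_ensembles) && length(ensembles)) {
    total <- sum(vapply(ensembles, function(en) en$fraction, numeric(1)))
    if (total > 1) fail("ensembles", "fractions must sum to <= 1 when disjoint")
  }
  if (!length(event_schedule)) fail("event_schedule", "must list at least one event")
  for (i in seq_along(event_schedule)) {
    sc <- event_schedule[[i]]
    if (is.null(sc$label)) fail(paste0("event_schedule[[", i, "]]$label"), "is required")
    if (is.null(sc$n_trials) || sc$n_trials < 1) {
      fail(paste0("event_schedule[[", i, "]]$n_trials"), "must be >= 1")
    }
    if (is.null(sc$duration) || sc$duration <= 0) {
      fail(paste0("event_schedule[[", i, "]]$duration"), "must be > 0")
    }
    if (is.null(sc$min_spacing) || sc$min_spacing <= 2 * epoch_half_s) {
      fail(paste0("event_schedule[[", i, "]]$min_spacing"),
           sprintf("must exceed 2 x epoch_half_s = %g s", 2 * epoch_half_s))
    }
  }
  structure(list(n_neurons = as.integer(n_neurons), frame_rate = frame_rate,
                 duration_s = duration_s, seed = as.integer(seed),
                 ensembles = ensembles, event_schedule = event_schedule,
                 kernel = kernel, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, baseline_f0 = baseline_f0,
                 baseline_spike_rate = baseline_spike_rate,
                 epoch_half_s = epoch_half_s,
                 shared_timeline = isTRUE(shared_timeline),
                 disjoint_ensembles = isTRUE(disjoint_ensembles)),
            class = "session_config")
}

# Causal convolution of a spike train with a kernel, zero history before t=0.
# Spike trains are sparse, so adding one kernel copy per spike beats a dense
# convolution by orders of magnitude.
causal_conv <- function(x, kern) {
  L <- length(kern)
  n <- length(x)
  out <- numeric(n)
  for (s in which(x != 0)) {
    len <- min(L, n - s + 1L)
    idx <- s:(s + len - 1L)
    out[idx] <- out[idx] + x[s] * kern[seq_len(len)]
  }
  out
}

# Unit-peak difference-of-exponentials calcium kernel sampled at fs, truncated
# where it decays below 1e-3 of peak.
calcium_kernel <- function(rise_tau, decay_tau, fs) {
  t_max <- decay_tau * log(1000)
  tt <- seq(0, t_max, by = 1 / fs)
  k <- exp(-tt / decay_tau) - exp(-tt / rise_tau)
  k / max(k)
}

# Sample event onsets uniformly subject to a minimum spacing, by drawing the
# free slack and re-inserting the mandatory gaps (exact, no rejection). The
# margin keeps full epochs (and kernel tails) inside the session.
sample_onsets <- function(n_trials, duration_s, min_spacing, event_dur, margin) {
  lo <- margin
  hi <- duration_s - margin - event_dur
  slack <- (hi - lo) - (n_trials - 1) * min_spacing
  if (hi <= lo || slack < 0) {
    stop("session too short for the requested event schedule: ",
         sprintf("%d trials at >= %g s spacing need %g s, have %g s",
                 n_trials, min_spacing, (n_trials - 1) * min_spacing,
                 max(hi - lo, 0)))
  }
  free <- sort(stats::runif(n_trials, 0, slack))
  lo + free + min_spacing * (seq_len(n_trials) - 1)
}

# Draw the session's event schedule. On a shared timeline all events are
# placed jointly with the largest requested spacing (a single behavioral
# stream: a mouse is not in two events at once), then labels are assigned by
# random permutation; otherwise each label's onsets are drawn independently.
draw_schedule <- function(config) {
  ev <- with_seed(derive_seed(config$seed, 17), {
    if (isTRUE(config$shared_timeline) && length(config$event_schedule) > 1) {
      n_each <- vapply(config$event_schedule, function(sc) sc$n_trials, numeric(1))
      spacing <- max(vapply(config$event_schedule,
                            function(sc) sc$min_spacing, numeric(1)))
      dur <- vapply(config$event_schedule, function(sc) sc$duration, numeric(1))
      onsets <- sample_onsets(sum(n_each), config$duration_s, spacing,
                              max(dur), margin = config$epoch_half_s)
      lab_idx <- sample(rep.int(seq_along(n_each), n_each))
      labels <- vapply(config$event_schedule, function(sc) sc$label, character(1))
      data.frame(label = labels[lab_idx], onset_s = onsets,
                 offset_s = onsets + dur[lab_idx])
    } else {
      do.call(rbind, lapply(config$event_schedule, function(sc) {
        on <- sample_onsets(sc$n_trials, config$duration_s, sc$min_spacing,
                            sc$duration, margin = config$epoch_half_s)
        data.frame(label = sc$label, onset_s = on, offset_s = on + sc$duration)
      }))
    }
  })
  event_table(ev$label, ev$onset_s, ev$offset_s)
}

#' Generate a synthetic imaging session with known ground truth
#'
#' @param config A `session_config`.
#' @return A list with `traces` (raw `trace_matrix`), `events`
#'   (`event_table`), and `ground_truth` (list with `responsive_map`:
#'   neuron -> character vector of event labels; `amplitudes`: neuron x event
#'   matrix in z units; `seed`). Calling twice with the same config is
#'   bit-identical.
#' @seealso [session_config()] for the signal model.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$frame_rate
  n_frames <- as.integer(round(config$duration_s * fs))
  n <- config$n_neurons
  kern <- calcium_kernel(config$kernel$rise_tau, config$kernel$decay_tau, fs)
  k_int <- sum(kern) / fs                     # integral of unit-peak kernel (s)

  # event schedule (own stream)
  events <- draw_schedule(config)

  # ensemble membership: decided per neuron from its own derived stream so the
  # assignment of neuron i never depends on how many neurons follow it. With
  # disjoint ensembles one uniform is partitioned by cumulative fractions;
  # otherwise membership draws are independent per ensemble.
  n_ens <- length(config$ensembles)
  member <- vector("list", n_ens)
  if (n_ens) {
    fracs <- vapply(config$ensembles, function(en) en$fraction, numeric(1))
    cuts <- cumsum(fracs)
    u <- vapply(seq_len(n), function(i) {
      with_seed(derive_seed(config$seed, 500000 + i), stats::runif(n_ens))
    }, numeric(n_ens))
    u <- matrix(u, nrow = n_ens)
    for (j in seq_len(n_ens)) {
      member[[j]] <- if (config$disjoint_ensembles) {
        which(u[1, ] >= c(0, cuts)[j] & u[1, ] < cuts[j])
      } else {
        which(u[j, ] < fracs[j])
      }
    }
  }
  labels <- vapply(config$ensembles, function(en) en$event, character(1))
  amp_mat <- matrix(0, n, length(unique(labels)),
                    dimnames = list(paste0("n", seq_len(n)), unique(labels)))
  responsive_map <- stats::setNames(vector("list", n), paste0("n", seq_len(n)))
  for (j in seq_along(member)) {
    amp_mat[member[[j]], labels[j]] <- config$ensembles[[j]]$amplitude
    for (i in member[[j]]) {
      responsive_map[[i]] <- union(responsive_map[[i]], labels[j])
    }
  }

  resp_rate <- 3 / fs                         # response spikes per frame
  x <- matrix(0, n, n_frames)
  for (i in seq_len(n)) {
    x[i, ] <- with_seed(derive_seed(config$seed, 1000 + i), {
      spikes <- numeric(n_frames)
      # background transients, identical statistics for every neuron
      bg <- stats::runif(n_frames) < config$baseline_spike_rate
      spikes[bg] <- spikes[bg] + config$noise_sd
      # event-locked transients
      for (j in seq_along(member)) {
        if (!(i %in% member[[j]])) next
        en <- config$ensembles[[j]]
        if (en$amplitude <= 0) next
        w_len <- en$window[2] - en$window[1]
        # amplitude calibration: mean added signal over the 5-s analysis
        # window ~= rate * w_len * k_int / 5 per unit spike height
        spike_amp <- en$amplitude * config$noise_sd * 5 /
          (resp_rate * fs * w_len * k_int)
        onsets <- events$onset_s[events$label == en$event]
        for (on in onsets) {
          shift <- if (en$jitter_sd > 0) stats::rnorm(1, 0, en$jitter_sd) else 0
          f0 <- session_frame(on + en$window[1] + shift, fs)
          f1 <- session_frame(on + en$window[2] + shift, fs) - 1L
          f0 <- max(f0, 1L); f1 <- min(f1, n_frames)
          if (f1 < f0) next
          idx <- f0:f1
          hit <- stats::runif(length(idx)) < resp_rate
          spikes[idx[hit]] <- spikes[idx[hit]] + spike_amp
        }
      }
      sig <- if (any(spikes != 0)) causal_conv(spikes, kern) else numeric(n_frames)
      # slow drift: random-phase sinusoid plus a smoothed random walk
      tt <- (seq_len(n_frames) - 1) / fs
      phase <- stats::runif(1, 0, 2 * pi)
      rw <- cumsum(stats::rnorm(n_frames))
      rw <- rw - mean(rw)
      rw <- rw / max(abs(rw), 1e-12)
      drift <- config$drift_amplitude *
        (0.5 * sin(2 * pi * tt / 300 + phase) + 0.5 * rw)
      config$baseline_f0 + drift + as.numeric(sig) +
        stats::rnorm(n_frames, 0, config$noise_sd)
    })
  }

  list(traces = trace_matrix(x, frame_rate = fs,
                             neuron_ids = paste0("n", seq_len(n)),
                             stage = "raw"),
       events = events,
       ground_truth = list(responsive_map = responsive_map,
                           amplitudes = amp_mat, seed = config$seed))
}

#' Generate a synthetic bulk photometry session
#'
#' Emulates a single-channel fiber-photometry recording (typically sampled at
#' 100 Hz) with a deterministic event-locked deflection of the given polarity
#' beginning `onset_lag` seconds after each event onset — e.g. an
#' extracellular-ATP sensor dips roughly 0.86 s after feeding-bout onset,
#' whereas a calcium sensor rises around onset. The deflection is the
#' session's calcium kernel scaled to `amplitude` (in units of `noise_sd`);
#' drift and noise are as in [generate_session()].
#'
#' @param config A `session_config`; `n_neurons` is ignored (one channel) and
#'   the first ensemble's `amplitude` sets the deflection size unless
#'   `amplitude` is given.
#' @param polarity `+1` (upward) or `-1` (downward deflection).
#' @param onset_lag Deflection latency after event onset, seconds
#'   (default 0.86).
#' @param amplitude Optional deflection amplitude override (z-like units).
#' @return A list with `traces` (1 x frames raw `trace_matrix`) and `events`.
#' @export
generate_photometry <- function(config, polarity = -1, onset_lag = 0.86,
                                amplitude = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (!polarity %in% c(-1, 1)) stop("invalid config: `polarity` must be +1 or -1")
  if (onset_lag < 0) stop("invalid config: `onset_lag` must be >= 0")
  if (is.null(amplitude)) {
    amplitude <- if (length(config$ensembles)) config$ensembles[[1]]$amplitude else 1
  }
  fs <- config$frame_rate
  n_frames <- as.integer(round(config$duration_s * fs))
  kern <- calcium_kernel(config$kernel$rise_tau, config$kernel$decay_tau, fs)

  events <- draw_schedule(config)

  x <- with_seed(derive_seed(config$seed, 53), {
    impulse <- numeric(n_frames)
    for (on in events$onset_s) {
      f <- session_frame(on + onset_lag, fs)
      if (f >= 1 && f <= n_frames) impulse[f] <- impulse[f] + 1
    }
    defl <- causal_conv(impulse, kern)
    tt <- (seq_len(n_frames) - 1) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    rw <- cumsum(stats::rnorm(n_frames))
    rw <- rw - mean(rw)
    rw <- rw / max(abs(rw), 1e-12)
    drift <- config$drift_amplitude *
      (0.5 * sin(2 * pi * tt / 300 + phase) + 0.5 * rw)
    config$baseline_f0 + drift +
      polarity * amplitude * config$noise_sd * as.numeric(defl) +
      stats::rnorm(n_frames, 0, config$noise_sd)
  })
  list(traces = trace_matrix(x, frame_rate = fs, neuron_ids = "photometry",
                             stage = "raw"),
       events = events)
}

#' Generate a synthetic place-preference behavior table
#'
#' Draws per-mouse occupancy of a reward-paired vs unpaired context, context
#' food intake, and feeding-bout intervals. The paired-side occupancy
#' proportion is `paired_bias` plus Gaussian noise, clamped to \[0, 1\], over a
#' 20-minute test.
#'
#' @param n_mice Number of mice.
#' @param paired_bias Expected paired-side occupancy proportion in \[0, 1\]
#'   (0.5 = indifferent).
#' @param occupancy_sd SD of the occupancy proportion across mice (default
#'   0.1; 0 makes occupancy deterministic).
#' @param intake_mean,intake_sd Named numeric `c(paired = , unpaired = )`
#'   intake moments in grams.
#' @param test_duration_s Test length in seconds (default 1200).
#' @param seed Integer seed.
#' @return A list with `mice` (data.frame: `mouse`, `t_paired`, `t_unpaired`,
#'   `cpp_score`, `intake_paired`, `intake_unpaired`) and `bouts` (data.frame
#'   of feeding-bout intervals per mouse).
#' @export
generate_behavior <- function(n_mice = 10, paired_bias = 0.5,
                              occupancy_sd = 0.1,
                              intake_mean = c(paired = 1.0, unpaired = 0.4),
                              intake_sd = c(paired = 0.2, unpaired = 0.1),
                              test_duration_s = 1200, seed = 1) {
  if (paired_bias < 0 || paired_bias > 1) {
    stop("invalid config: `paired_bias` must be in [0, 1]")
  }
  with_seed(seed, {
    prop <- pmin(1, pmax(0, stats::rnorm(n_mice, paired_bias, occupancy_sd)))
    t_paired <- prop * test_duration_s
    t_unpaired <- (1 - prop) * test_duration_s
    mice <- data.frame(
      mouse = paste0("m", seq_len(n_mice)),
      t_paired = t_paired, t_unpaired = t_unpaired,
      cpp_score = (t_paired - t_unpaired) / (t_paired + t_unpaired),
      intake_paired = pmax(0, stats::rnorm(n_mice, intake_mean[["paired"]],
                                           intake_sd[["paired"]])),
      intake_unpaired = pmax(0, stats::rnorm(n_mice, intake_mean[["unpaired"]],
                                             intake_sd[["unpaired"]])),
      stringsAsFactors = FALSE)
    bouts <- do.call(rbind, lapply(seq_len(n_mice), function(i) {
      n_bouts <- 1 + stats::rpois(1, 8)
      starts <- sort(stats::runif(n_bouts, 0, test_duration_s - 30))
      durs <- stats::rexp(n_bouts, rate = 1 / 8) + 1
      data.frame(mouse = paste0("m", i), start_s = starts,
                 end_s = pmin(starts + durs, test_duration_s))
    }))
    list(mice = mice, bouts = bouts)
  })
}
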