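#' Fractional fluorescence change (delta-F/F)
#'
#' Converts raw fluorescence to the fractional change `(F - F0) / F0`, where
#' `F0` is the mean baseline fluorescence of each neuron. By default `F0` is
#' the session-wide mean; a baseline window in session seconds can be supplied
#' instead (e.g. a quiet period at the start of the recording).
#'
#' @param raw A `trace_matrix` at stage `"raw"`.
#' @param f0_window Optional `window_spec` (or numeric `c(t0, t1)`) in session
#'   seconds over which `F0` is averaged; `NULL` uses the whole session.
#' @return A `trace_matrix` at stage `"dff"`. The per-neuron baselines are
#'   attached as attribute `"f0"`.
#' @details `F0 <= 0` for any neuron is a degenerate baseline (the fractional
#'   change loses meaning) and is an error naming the offending neuron.
#' @export
compute_dff <- function(raw, f0_window = NULL) {
  if (!inherits(raw, "trace_matrix")) stop("`raw` must be a trace_matrix")
  if (trace_stage(raw) != "raw") stop("`raw` must be at stage \"raw\"")
  fs <- frame_rate(raw)
  if (is.null(f0_window)) {
    f0 <- rowMeans(raw)
  } else {
    w <- as_window(f0_window)
    idx <- window_frames(w, align_index = 0L, n_frames = ncol(raw), fs = fs)
    f0 <- rowMeans(raw[, idx, drop = FALSE])
  }
  bad <- which(f0 <= 0)
  if (length(bad)) {
    stop("degenerate baseline: F0 <= 0 for neuron(s) ",
         paste(neuron_ids(raw)[bad], collapse = ", "))
  }
  trace_matrix(sweep(sweep(unclass(raw), 1, f0, "-"), 1, f0, "/"),
               frame_rate = fs, neuron_ids = neuron_ids(raw), stage = "dff") |>
    structure(f0 = f0)
}

#' Z-score traces per neuron over the session
#'
#' Standardizes each neuron's trace over the full session so that activity is
#' expressed in standard-deviation units. The population SD convention
#' (divide by n, not n - 1) is used throughout the package.
#'
#' @param traces A `trace_matrix` (any stage; typically `"dff"`).
#' @return A `trace_matrix` at stage `"zscored"`. Neurons with zero SD
#'   (constant traces) cannot be standardized; they are dropped with a warning
#'   and listed in the `"excluded"` attribute rather than silently zeroed.
#' @export
zscore_traces <- function(traces) {
  if (!inherits(traces, "trace_matrix")) stop("`traces` must be a trace_matrix")
  v <- unclass(traces)
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans(sweep(v, 1, mu, "-")^2))
  degenerate <- sd_pop <= 0
  if (all(degenerate)) stop("all neurons have zero SD; nothing to z-score")
  if (any(degenerate)) {
    warning("excluding ", sum(degenerate), " zero-SD neuron(s): ",
            paste(neuron_ids(traces)[degenerate], collapse = ", "))
  }
  keep <- !degenerate
  z <- sweep(sweep(v[keep, , drop = FALSE], 1, mu[keep], "-"), 1, sd_pop[keep], "/")
  out <- trace_matrix(z, frame_rate = frame_rate(traces),
                      neuron_ids = neuron_ids(traces)[keep], stage = "zscored")
  attr(out, "excluded") <- neuron_ids(traces)[degenerate]
  out
}

#' Extract peri-event epochs
#'
#' Slices a fixed window of trace data around every onset of one event label,
#' producing a neuron x trial x frame tensor aligned on onset. With the 30 Hz
#' miniscope default of 10 s before and 10 s after onset each epoch holds
#' exactly 600 frames. Trials whose window would reach outside the session are
#' excluded (never padded) and the exclusion count is recorded.
#'
#' @param traces A `trace_matrix`, typically z-scored (photometry pipelines may
#'   pass stage `"dff"`).
#' @param events An `event_table`.
#' @param label Event label to align on.
#' @param pre_s,post_s Seconds of data before / after onset (defaults 10/10).
#' @return An `epoch_tensor`: a 3-D array (neuron x trial x frame) with
#'   attributes `pre_s`, `post_s`, `frame_rate`, `align_index` (0-based frame
#'   of onset within the epoch), `trial_event_ids` (row indices into the label
#'   subset), `n_excluded`, and `label`.
#' @export
extract_epochs <- function(traces, events, label, pre_s = 10, post_s = 10) {
  if (!inherits(traces, "trace_matrix")) stop("`traces` must be a trace_matrix")
  if (pre_s < 0 || post_s <= 0) stop("`pre_s` must be >= 0 and `post_s` > 0")
  ev <- events[events$label == label, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events with label \"", label, "\"")
  fs <- frame_rate(traces)
  n_frames <- as.integer(round((pre_s + post_s) * fs))
  align <- as.integer(round(pre_s * fs))
  onset_frame <- session_frame(ev$onset_s, fs)
  start <- onset_frame - align
  end <- start + n_frames - 1L
  ok <- start >= 1L & end <= ncol(traces)
  if (!any(ok)) stop("no usable trials: every epoch overlaps a session edge")
  kept <- which(ok)
  x <- array(NA_real_, dim = c(nrow(traces), length(kept), n_frames),
             dimnames = list(neuron_ids(traces), NULL, NULL))
  for (i in seq_along(kept)) {
    x[, i, ] <- unclass(traces)[, start[kept[i]]:end[kept[i]], drop = FALSE]
  }
  structure(x,
            pre_s = pre_s, post_s = post_s, frame_rate = fs,
            align_index = align, trial_event_ids = kept,
            trial_onsets_s = ev$onset_s[kept],
            n_excluded = sum(!ok), label = label,
            neuron_ids = neuron_ids(traces), stage = trace_stage(traces),
            class = c("epoch_tensor", "array"))
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<epoch_tensor> %d neurons x %d trials x %d frames @ %g Hz [label=%s, -%g/+%g s, %d excluded]\n",
    d[1], d[2], d[3], frame_rate(x), attr(x, "label"),
    attr(x, "pre_s"), attr(x, "post_s"), attr(x, "n_excluded")))
  invisible(x)
}

#' Windowed per-trial statistics of an epoch tensor
#'
#' Reduces an onset-relative window of each trial to a scalar per neuron:
#' the mean, the maximum, or the area under the curve (trapezoidal integral of
#' activity against time, in z * s). For the AUC the sample sitting exactly at
#' `t1` is used as the right integration endpoint when it exists inside the
#' epoch, so a constant value c over a 5 s window integrates to exactly 5c.
#'
#' @param epochs An `epoch_tensor`.
#' @param window A `window_spec` (or `c(t0, t1)`) relative to onset, inside the
#'   epoch bounds.
#' @param stat `"mean"`, `"max"`, or `"auc"`.
#' @return A neuron x trial numeric matrix.
#' @export
window_stat <- function(epochs, window, stat = c("mean", "max", "auc")) {
  stat <- match.arg(stat)
  if (!inherits(epochs, "epoch_tensor")) stop("`epochs` must be an epoch_tensor")
  fs <- frame_rate(epochs)
  d <- dim(epochs)
  idx <- window_frames(window, attr(epochs, "align_index"), d[3], fs)
  if (stat == "auc" && max(idx) < d[3]) idx <- c(idx, max(idx) + 1L)
  slab <- epochs[, , idx, drop = FALSE]
  out <- switch(stat,
    mean = apply(slab, c(1, 2), mean),
    max  = apply(slab, c(1, 2), max),
    auc  = {
      tt <- (idx - 1 - attr(epochs, "align_index")) / fs
      apply(slab, c(1, 2), function(v) pracma::trapz(tt, v))
    })
  dimnames(out) <- list(attr(epochs, "neuron_ids"), NULL)
  out
}

#' Response onset latency of a single-channel signal
#'
#' Finds the first sample after the baseline period that exceeds the baseline
#' mean by more than two baseline standard deviations — upward for
#' positive-going sensors, downward for negative-going ones (e.g. extracellular
#' ATP sensors whose fluorescence drops during feeding bouts).
#'
#' @param values Numeric vector (e.g. a trial-averaged peri-event trace) or a
#'   single-row `trace_matrix`.
#' @param times Sample times in seconds (same length as `values`). If `values`
#'   is a `trace_matrix` the session clock is used; for onset-relative traces
#'   pass `frame_times()` of the epoch tensor.
#' @param baseline `window_spec` on the same clock as `times`; must contain at
#'   least 2 samples with nonzero SD.
#' @param direction `"above"` or `"below"` the baseline band.
#' @param n_sd Width of the detection band in baseline SDs (default 2).
#' @return Time (s) of the first crossing after the baseline window, or `NA`
#'   if the signal never leaves the band.
#' @export
onset_latency <- function(values, times = NULL,
                          baseline = window_spec(-5, 0),
                          direction = c("above", "below"), n_sd = 2) {
  direction <- match.arg(direction)
  if (inherits(values, "trace_matrix")) {
    if (nrow(values) != 1L) stop("`values` must be single-channel")
    if (is.null(times)) times <- frame_times(values)
    values <- as.numeric(values)
  }
  if (is.null(times)) stop("`times` required for a plain numeric series")
  if (length(times) != length(values)) stop("`times` and `values` lengths differ")
  w <- as_window(baseline)
  base <- values[times >= w$t0 & times < w$t1]
  if (length(base) < 2L) stop("baseline window holds fewer than 2 samples")
  mu <- mean(base)
  sd_b <- sqrt(mean((base - mu)^2))
  if (sd_b <= 0) stop("degenerate baseline: zero SD in the baseline window")
  post <- which(times >= w$t1)
  crossed <- if (direction == "above") values[post] > mu + n_sd * sd_b
             else values[post] < mu - n_sd * sd_b
  if (!any(crossed)) return(NA_real_)
  times[post[which(crossed)[1]]]
}
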