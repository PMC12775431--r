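#' Construct a trace matrix
#'
#' The universal signal container: a neuron x frame real matrix with its
#' sampling rate, neuron identifiers, and processing stage. Fluorescence is
#' stored in arbitrary units at stage `"raw"`, as the dimensionless fractional
#' change at stage `"dff"`, and in standard-deviation units at stage
#' `"zscored"`.
#'
#' @param values Numeric matrix, neurons in rows, frames in columns. A vector
#'   is treated as a single-channel (one-row) recording.
#' @param frame_rate Sampling rate in Hz (> 0).
#' @param neuron_ids Character vector of row identifiers; defaults to
#'   `"n1"..."nN"`.
#' @param stage One of `"raw"`, `"dff"`, `"zscored"`.
#' @return A `trace_matrix`: the matrix with `frame_rate`, `neuron_ids` and
#'   `stage` attributes.
#' @export
trace_matrix <- function(values, frame_rate,
                         neuron_ids = NULL,
                         stage = c("raw", "dff", "zscored")) {
  stage <- match.arg(stage)
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (neurons x frames)")
  }
  if (!all(is.finite(values))) stop("trace values must all be finite")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number (Hz)")
  }
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(values)))
  if (length(neuron_ids) != nrow(values)) {
    stop("`neuron_ids` length must equal the number of rows")
  }
  rownames(values) <- neuron_ids
  structure(values,
            frame_rate = frame_rate,
            neuron_ids = as.character(neuron_ids),
            stage = stage,
            class = c("trace_matrix", "matrix", "array"))
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d neurons x %d frames @ %g Hz, stage=%s (%.1f s)\n",
              nrow(x), ncol(x), frame_rate(x), trace_stage(x),
              ncol(x) / frame_rate(x)))
  invisible(x)
}

#' Accessors for trace matrices and epoch tensors
#'
#' @param x A `trace_matrix` or `epoch_tensor`.
#' @return `frame_rate()` the sampling rate in Hz; `trace_stage()` the
#'   processing stage; `neuron_ids()` the neuron identifiers;
#'   `frame_times()` the frame time stamps in seconds (session clock for a
#'   `trace_matrix`, onset-relative for an `epoch_tensor`).
#' @export
frame_rate <- function(x) attr(x, "frame_rate")

#' @rdname frame_rate
#' @export
trace_stage <- function(x) attr(x, "stage")

#' @rdname frame_rate
#' @export
neuron_ids <- function(x) attr(x, "neuron_ids")

#' @rdname frame_rate
#' @export
frame_times <- function(x) {
  if (inherits(x, "epoch_tensor")) {
    (seq_len(dim(x)[3]) - 1L - attr(x, "align_index")) / frame_rate(x)
  } else {
    (seq_len(ncol(x)) - 1L) / frame_rate(x)
  }
}

#' Construct a behavioral event table
#'
#' Labeled behavioral onsets (and optional offsets) on the session timeline,
#' e.g. chamber entries or feeding bouts annotated from synchronized video.
#'
#' @param label Character vector of event labels.
#' @param onset_s Numeric onsets in seconds (>= 0).
#' @param offset_s Optional numeric offsets in seconds (`NA` where the event is
#'   a point event); must satisfy `offset_s >= onset_s` where present.
#' @return A `data.frame` of class `event_table` with columns `label`,
#'   `onset_s`, `offset_s`, sorted by onset within label.
#' @export
event_table <- function(label, onset_s, offset_s = NA_real_) {
  onset_s <- as.numeric(onset_s)
  if (length(label) == 1L) label <- rep_len(label, length(onset_s))
  label <- as.character(label)
  offset_s <- rep_len(as.numeric(offset_s), length(onset_s))
  if (length(label) != length(onset_s)) stop("`label` and `onset_s` lengths differ")
  if (any(onset_s < 0)) stop("onsets must be >= 0")
  bad <- !is.na(offset_s) & offset_s < onset_s
  if (any(bad)) stop("offset_s must be >= onset_s (rows ",
                     paste(which(bad), collapse = ", "), ")")
  out <- data.frame(label = label, onset_s = onset_s, offset_s = offset_s,
                    stringsAsFactors = FALSE)
  out <- out[order(out$label, out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Define an onset-relative analysis window
#'
#' Windows are half-open intervals `[t0, t1)` in seconds relative to event
#' onset; the half-open convention prevents a frame shared by two abutting
#' windows (e.g. baseline `[-5, 0)` and event `[0, 5)`) from being counted
#' twice.
#'
#' @param t0,t1 Window bounds in seconds, `t0 < t1`.
#' @return A `window_spec` list with elements `t0` and `t1`.
#' @export
window_spec <- function(t0, t1) {
  if (!is.numeric(t0) || !is.numeric(t1) || length(t0) != 1L || length(t1) != 1L) {
    stop("window bounds must be single numbers")
  }
  if (!(t0 < t1)) stop("window requires t0 < t1, got [", t0, ", ", t1, ")")
  structure(list(t0 = t0, t1 = t1), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window> [%g, %g) s\n", x$t0, x$t1))
  invisible(x)
}

as_window <- function(w) {
  if (inherits(w, "window_spec")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(window_spec(w[1], w[2]))
  stop("expected a window_spec or numeric length-2 vector")
}

# 1-based frame index covering session time t: frame = floor(t * fs) + 1
session_frame <- function(t, fs) as.integer(floor(t * fs + 1e-9)) + 1L

# Frame indices of an epoch (1..T, align 0-based) falling in [t0, t1)
window_frames <- function(window, align_index, n_frames, fs) {
  w <- as_window(window)
  j0 <- as.integer(ceiling(align_index + fs * w$t0 + 1 - 1e-9))
  j1 <- as.integer(ceiling(align_index + fs * w$t1 + 1 - 1e-9)) - 1L
  if (j0 < 1L || j1 > n_frames) {
    stop(sprintf("window [%g, %g) lies outside the epoch", w$t0, w$t1))
  }
  if (j1 < j0) stop("window covers no frames at this frame rate")
  j0:j1
}

# Derive a child seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
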