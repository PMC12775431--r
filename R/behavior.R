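#' Conditioned place preference score
#'
#' `(t_paired - t_unpaired) / (t_paired + t_unpaired)`: +1 means all test time
#' was spent in the reward-paired context, -1 all in the unpaired context, and
#' 0 indifference.
#'
#' @param t_paired,t_unpaired Occupancy times in seconds (vectors recycle);
#'   both nonnegative and their sum must be positive.
#' @return Numeric score(s) in `[-1, 1]`.
#' @export
cpp_score <- function(t_paired, t_unpaired) {
  if (any(t_paired < 0) || any(t_unpaired < 0)) stop("occupancy times must be >= 0")
  total <- t_paired + t_unpaired
  if (any(total <= 0)) stop("undefined score: total occupancy must be > 0")
  (t_paired - t_unpaired) / total
}

#' Correlate a neural metric with a behavioral metric
#'
#' Thin wrapper around [stats::cor.test()] used to couple per-trial neural
#' quantities (e.g. event-window AUC of the activated ensemble) to per-trial
#' behavior (e.g. feeding-bout duration). Incomplete pairs are dropped and the
#' effective n reported. P-values are two-sided and uncorrected; any
#' multiple-testing correction is the caller's responsibility.
#'
#' @param x,y Equal-length numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p_value`, `n`, `method`.
#' @export
correlate_metric <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in an input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

#' Summarize feeding bouts for one event label
#'
#' Collects the bout intervals of one label into a duration table. Overlapping
#' bouts (common in hand-annotated files) are merged into their union with a
#' warning rather than rejected.
#'
#' @param events An `event_table`; every row of `label` must carry an offset.
#' @param label Bout label (e.g. the feeding-bout event).
#' @return List with `bouts` (data.frame `start_s`, `end_s`, `duration_s`),
#'   `total_s`, and `n_bouts`.
#' @export
summarize_bouts <- function(events, label) {
  ev <- events[events$label == label, , drop = FALSE]
  if (!nrow(ev)) {
    return(list(bouts = data.frame(start_s = numeric(0), end_s = numeric(0),
                                   duration_s = numeric(0)),
                total_s = 0, n_bouts = 0L))
  }
  miss <- which(is.na(ev$offset_s))
  if (length(miss)) stop("missing offsets for \"", label, "\" rows ",
                         paste(miss, collapse = ", "))
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  start <- ev$onset_s[1]; end <- ev$offset_s[1]
  starts <- ends <- numeric(0)
  merged <- FALSE
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev$onset_s[i] <= end) {
      end <- max(end, ev$offset_s[i]); merged <- TRUE
    } else {
      starts <- c(starts, start); ends <- c(ends, end)
      start <- ev$onset_s[i]; end <- ev$offset_s[i]
    }
  }
  starts <- c(starts, start); ends <- c(ends, end)
  if (merged) warning("overlapping bouts merged (", nrow(ev), " -> ",
                      length(starts), ")")
  bouts <- data.frame(start_s = starts, end_s = ends,
                      duration_s = ends - starts)
  list(bouts = bouts, total_s = sum(bouts$duration_s),
       n_bouts = nrow(bouts))
}
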