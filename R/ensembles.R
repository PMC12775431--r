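#' Detect event-activated neurons by within-trial permutation test
#'
#' For each neuron the observed statistic is the trial-mean difference between
#' the event-window and baseline-window response (per-trial `statistic` over
#' the window frames). The null is built by randomly exchanging the
#' baseline/event window labels within each trial — the exchange flips the sign
#' of that trial's difference — and the one-sided p-value is
#' `(1 + #{null >= observed}) / (n_perm + 1)`. A neuron is called activated
#' only if it both survives the permutation test (`p < alpha`) and its mean
#' event-window z-scored response exceeds `z_threshold`; the magnitude rule is
#' conjunctive, so a tiny-but-significant response is not an activation.
#'
#' @param epochs An `epoch_tensor` of z-scored activity with >= 2 trials.
#' @param baseline,event Onset-relative `window_spec`s (defaults `[-5, 0)` and
#'   `[0, 5)`); they must not overlap.
#' @param n_perm Number of label reassignments (default 1000). Ignored when
#'   `exact = TRUE`.
#' @param alpha Significance level for the permutation test (default 0.05).
#' @param z_threshold Minimum mean event-window response, in SD units
#'   (default 0.2). Set to `-Inf` to test the permutation component alone.
#' @param statistic Per-trial window reduction: `"mean"` (default) or `"max"`.
#' @param seed Optional integer fixing the permutation draws.
#' @param exact If `TRUE`, enumerate all `2^n_trials` window-label assignments
#'   (requires <= 20 trials) and report the exact permutation p-value
#'   `#{null >= observed} / 2^n_trials` with no Monte-Carlo smoothing.
#' @return An `activation_result`: a data.frame with one row per neuron
#'   (`neuron`, `p_value`, `response`, `observed`, `activated`) and the test
#'   parameters in attribute `"params"`.
#' @export
detect_activated <- function(epochs,
                             baseline = window_spec(-5, 0),
                             event = window_spec(0, 5),
                             n_perm = 1000, alpha = 0.05, z_threshold = 0.2,
                             statistic = c("mean", "max"),
                             seed = NULL, exact = FALSE) {
  statistic <- match.arg(statistic)
  baseline <- as_window(baseline); event <- as_window(event)
  if (max(baseline$t0, event$t0) < min(baseline$t1, event$t1)) {
    stop("baseline and event windows overlap")
  }
  n_trials <- dim(epochs)[2]
  if (n_trials < 2L) stop("insufficient data: need >= 2 trials")
  b <- window_stat(epochs, baseline, stat = statistic)
  e <- window_stat(epochs, event, stat = statistic)
  d <- e - b                                  # neurons x trials
  observed <- rowMeans(d)
  response <- rowMeans(e)

  if (exact) {
    if (n_trials > 20L) stop("exact enumeration limited to <= 20 trials")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_trials)))
    null_stats <- d %*% t(signs) / n_trials   # neurons x 2^n
    p <- rowMeans(null_stats >= observed - 1e-12)
    n_perm <- ncol(signs)
  } else {
    if (n_perm < 1L) stop("`n_perm` must be >= 1")
    p <- with_seed(seed, {
      vapply(seq_len(nrow(d)), function(i) {
        s <- matrix(sample(c(-1, 1), n_perm * n_trials, replace = TRUE),
                    n_perm, n_trials)
        null_i <- as.numeric(s %*% d[i, ]) / n_trials
        (1 + sum(null_i >= observed[i] - 1e-12)) / (n_perm + 1)
      }, numeric(1))
    })
  }

  out <- data.frame(neuron = rownames(d), p_value = p, response = response,
                    observed = observed,
                    activated = p < alpha & response > z_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "params") <- list(baseline = unclass(baseline), event = unclass(event),
                              n_perm = n_perm, alpha = alpha,
                              z_threshold = z_threshold, statistic = statistic,
                              scheme = "within-trial window-label exchange",
                              exact = exact, seed = seed)
  class(out) <- c("activation_result", "data.frame")
  out
}

#' Selectivity response index between two events
#'
#' `SRI = (A - B) / (A + B)` where `A` and `B` are each neuron's average
#' z-scored response in the response periods of events A and B. The index
#' lives in `[-1, 1]` when both responses are nonnegative; when the
#' denominator is nonpositive or negligibly small (`A + B <= eps`) the index
#' loses that interpretation and is reported as `NA` (undefined).
#'
#' @param A,B Named numeric vectors of mean event-window responses for the
#'   same registered neurons (names must match as sets).
#' @param eps Degeneracy guard on the denominator (default 1e-6).
#' @return Named numeric vector of SRI values (`NA` = undefined), aligned to
#'   the names of `A`.
#' @export
compute_sri <- function(A, B, eps = 1e-6) {
  if (is.null(names(A)) != is.null(names(B))) stop("A and B must both be named or both unnamed")
  if (!is.null(names(A))) {
    if (!setequal(names(A), names(B))) stop("registration error: neuron sets differ")
    B <- B[names(A)]
  } else if (length(A) != length(B)) stop("registration error: lengths differ")
  sri <- (A - B) / (A + B)
  sri[(A + B) <= eps] <- NA_real_
  sri
}

#' Classify selectivity from SRI values
#'
#' Cells with SRI above the threshold are selective for event A, below the
#' negated threshold selective for event B, and in between are shared
#' (activated in both events). Undefined (`NA`) SRIs map to `"undefined"`.
#'
#' @param sri Numeric vector from [compute_sri()].
#' @param threshold Cut-off magnitude (default 0.2).
#' @return Factor with levels `A_selective`, `B_selective`, `shared`,
#'   `undefined`.
#' @export
classify_selectivity <- function(sri, threshold = 0.2) {
  out <- rep("shared", length(sri))
  out[sri > threshold] <- "A_selective"
  out[sri < -threshold] <- "B_selective"
  out[is.na(sri)] <- "undefined"
  factor(out, levels = c("A_selective", "B_selective", "shared", "undefined"))
}

#' Phenotype pre-cells and post-cells around feeding-bout onset
#'
#' Pre-cells are activated in the 5 s leading up to bout onset (event window
#' `[-5, 0)` tested against baseline `[-10, -5)`); post-cells in the 5 s after
#' onset (event `[0, 5)` against baseline `[-5, 0)`). Both tests use the same
#' permutation machinery as [detect_activated()] with the per-trial maximum as
#' the window statistic, and a cell passes only if its trial-mean maximum
#' z-scored response in the event window exceeds `z_threshold`. A neuron
#' passing both tests is assigned to the phase with the larger event-window
#' maximum (tie goes to pre), keeping the two groups disjoint.
#'
#' @inheritParams detect_activated
#' @return A `data.frame` with columns `neuron`, `phase`
#'   (`pre`/`post`/`neither`), `max_response_pre`, `max_response_post`,
#'   `p_pre`, `p_post`.
#' @export
identify_phase_cells <- function(epochs, n_perm = 1000, alpha = 0.05,
                                 z_threshold = 0.2, seed = NULL) {
  if (attr(epochs, "pre_s") < 10 || attr(epochs, "post_s") < 5) {
    stop("epochs must span at least [-10, +5] s around onset")
  }
  pre_res <- detect_activated(epochs,
                              baseline = window_spec(-10, -5),
                              event = window_spec(-5, 0),
                              n_perm = n_perm, alpha = alpha,
                              z_threshold = z_threshold, statistic = "max",
                              seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  post_res <- detect_activated(epochs,
                               baseline = window_spec(-5, 0),
                               event = window_spec(0, 5),
                               n_perm = n_perm, alpha = alpha,
                               z_threshold = z_threshold, statistic = "max",
                               seed = if (is.null(seed)) NULL else derive_seed(seed, 2))
  phase <- rep("neither", nrow(pre_res))
  phase[pre_res$activated] <- "pre"
  phase[post_res$activated & !pre_res$activated] <- "post"
  both <- pre_res$activated & post_res$activated
  phase[both] <- ifelse(post_res$response[both] > pre_res$response[both],
                        "post", "pre")
  data.frame(neuron = pre_res$neuron,
             phase = factor(phase, levels = c("pre", "post", "neither")),
             max_response_pre = pre_res$response,
             max_response_post = post_res$response,
             p_pre = pre_res$p_value, p_post = post_res$p_value,
             stringsAsFactors = FALSE)
}

#' Join per-neuron results across two sessions via a correspondence table
#'
#' Cross-session cell matching (e.g. spatial-footprint registration) is an
#' external input; this join consumes its output table and inner-joins two
#' per-neuron result tables on the matched identities.
#'
#' @param results_a,results_b Data frames with a `neuron` column (e.g.
#'   `activation_result`s).
#' @param mapping Data frame with columns `id_a`, `id_b`; must be injective in
#'   both directions (no duplicate ids on either side).
#' @return A list with `matched` (joined data.frame; columns suffixed `_a` /
#'   `_b`), `unmatched_a`, and `unmatched_b` (character vectors of neuron ids
#'   with no counterpart).
#' @export
join_registered <- function(results_a, results_b, mapping) {
  if (!all(c("id_a", "id_b") %in% names(mapping))) {
    stop("mapping must have columns id_a, id_b")
  }
  if (anyDuplicated(mapping$id_a) || anyDuplicated(mapping$id_b)) {
    stop("mapping error: duplicate ids in the correspondence table")
  }
  a <- results_a[match(mapping$id_a, results_a$neuron), , drop = FALSE]
  b <- results_b[match(mapping$id_b, results_b$neuron), , drop = FALSE]
  ok <- !is.na(a$neuron) & !is.na(b$neuron)
  matched <- cbind(stats::setNames(a[ok, , drop = FALSE],
                                   paste0(names(a), "_a")),
                   stats::setNames(b[ok, , drop = FALSE],
                                   paste0(names(b), "_b")))
  rownames(matched) <- NULL
  list(matched = matched,
       unmatched_a = setdiff(results_a$neuron, mapping$id_a[ok]),
       unmatched_b = setdiff(results_b$neuron, mapping$id_b[ok]))
}
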