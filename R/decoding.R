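#' Assemble a labeled trial tensor from two epoch sets
#'
#' Stacks the peri-event epochs of two events into a single N x M x T activity
#' array (N neurons, M trials, T frames) with binary behavior labels (event A
#' = 1, event B = 0) — the container the population decoders consume.
#'
#' @param epochs_a,epochs_b `epoch_tensor`s sharing neuron ids and the same
#'   frame grid (frame rate, pre/post spans).
#' @param neuron_subset Neuron ids to keep, typically the activated set; must
#'   be non-empty and present in both epoch sets.
#' @return A `trial_tensor`: list with `activity` (N x M x T array), `labels`
#'   (0/1 integer vector of length M), `frame_rate`, `align_index`, `pre_s`,
#'   `post_s`, `label_a`, `label_b`.
#' @export
build_trial_tensor <- function(epochs_a, epochs_b, neuron_subset) {
  for (at in c("frame_rate", "align_index", "pre_s", "post_s")) {
    if (!isTRUE(all.equal(attr(epochs_a, at), attr(epochs_b, at)))) {
      stop("alignment error: epoch sets differ in ", at)
    }
  }
  if (dim(epochs_a)[3] != dim(epochs_b)[3]) {
    stop("alignment error: epoch sets differ in frame count")
  }
  neuron_subset <- as.character(neuron_subset)
  if (!length(neuron_subset)) stop("`neuron_subset` must be non-empty")
  ids_a <- attr(epochs_a, "neuron_ids"); ids_b <- attr(epochs_b, "neuron_ids")
  if (!all(neuron_subset %in% ids_a) || !all(neuron_subset %in% ids_b)) {
    stop("alignment error: neuron_subset not present in both epoch sets")
  }
  a <- epochs_a[match(neuron_subset, ids_a), , , drop = FALSE]
  b <- epochs_b[match(neuron_subset, ids_b), , , drop = FALSE]
  m_a <- dim(a)[2]; m_b <- dim(b)[2]
  activity <- array(NA_real_, dim = c(length(neuron_subset), m_a + m_b, dim(a)[3]),
                    dimnames = list(neuron_subset, NULL, NULL))
  activity[, seq_len(m_a), ] <- a
  activity[, m_a + seq_len(m_b), ] <- b
  structure(list(activity = activity,
                 labels = c(rep(1L, m_a), rep(0L, m_b)),
                 frame_rate = attr(epochs_a, "frame_rate"),
                 align_index = attr(epochs_a, "align_index"),
                 pre_s = attr(epochs_a, "pre_s"), post_s = attr(epochs_a, "post_s"),
                 label_a = attr(epochs_a, "label"), label_b = attr(epochs_b, "label")),
            class = "trial_tensor")
}

# Per-trial feature matrix (M x p) from a trial tensor: per-neuron mean over an
# onset-relative window (default), or the flattened N x T frame profile.
tensor_features <- function(tensor, feature_window = c(0, 5), flatten = FALSE) {
  act <- tensor$activity
  if (flatten) return(t(apply(act, 2, as.numeric)))
  idx <- window_frames(feature_window, tensor$align_index, dim(act)[3],
                       tensor$frame_rate)
  t(apply(act[, , idx, drop = FALSE], c(1, 2), mean))
}

# Stratified fold assignment; assumes RNG already seeded by the caller.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample(seq_len(k)), length(idx))
  }
  fold
}

# Linear maximum-margin fit with class-balanced weights on a standardized
# feature matrix; returns the hyperplane oriented so class 1 is positive.
fit_linear_svm <- function(x, y) {
  yf <- factor(y, levels = c(0, 1))
  n <- length(y)
  cw <- n / (2 * table(yf))
  model <- e1071::svm(x, yf, kernel = "linear", cost = 1, scale = FALSE,
                      class.weights = cw)
  w <- drop(t(model$coefs) %*% model$SV)
  b <- -model$rho
  dv <- drop(x %*% w) + b
  if (mean(dv[y == 1]) < mean(dv[y == 0])) { w <- -w; b <- -b }
  list(model = model, w = w, b = b)
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd <= 0] <- 1
  list(mu = mu, sd = sd,
       apply = function(z) sweep(sweep(z, 2, mu, "-"), 2, sd, "/"))
}

#' Cross-validated binary population decoding
#'
#' Trains a linear maximum-margin classifier to predict the behavior label
#' from population activity, with stratified k-fold cross-validation (default
#' 10-fold). Features are standardized inside each training fold only, so no
#' test information leaks into the fit. Decoder performance is the fraction of
#' correctly predicted held-out labels.
#'
#' @param tensor A `trial_tensor`.
#' @param folds Number of CV folds (default 10). If the smaller class has
#'   fewer trials the fold count is reduced (minimum 2) with a warning.
#' @param seed Optional integer fixing the fold assignment.
#' @param feature_window Onset-relative window `c(t0, t1)` over which each
#'   neuron's activity is averaged into one feature (default `[0, 5)`).
#' @param flatten If `TRUE`, use the full flattened N x T frame profile as the
#'   feature vector instead of windowed means.
#' @return A `decoder_output`: list with `fold_accuracies`, `mean_accuracy`,
#'   `folds`, `weights`, `intercept` (hyperplane fit on all standardized
#'   data, positive side = event A), `feature`, `seed`.
#' @export
decode_cv <- function(tensor, folds = 10, seed = NULL,
                      feature_window = c(0, 5), flatten = FALSE) {
  stopifnot(inherits(tensor, "trial_tensor"))
  y <- tensor$labels
  if (length(unique(y)) < 2L) stop("label error: both classes must be present")
  x <- tensor_features(tensor, feature_window, flatten)
  min_class <- min(table(y))
  if (min_class < folds) {
    folds <- max(2L, min_class)
    warning("reducing folds to ", folds, " (smallest class has ", min_class,
            " trials)")
  }
  fold <- with_seed(seed, stratified_folds(y, folds))
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fold != k; te <- fold == k
    std <- standardizer(x[tr, , drop = FALSE])
    fit <- fit_linear_svm(std$apply(x[tr, , drop = FALSE]), y[tr])
    pred <- as.integer(drop(std$apply(x[te, , drop = FALSE]) %*% fit$w) + fit$b > 0)
    mean(pred == y[te])
  }, numeric(1))
  std_all <- standardizer(x)
  fit_all <- fit_linear_svm(std_all$apply(x), y)
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 folds = folds, weights = fit_all$w, intercept = fit_all$b,
                 feature = if (flatten) "flatten" else
                   sprintf("mean[%g,%g)", feature_window[1], feature_window[2]),
                 seed = seed),
            class = "decoder_output")
}

#' @export
print.decoder_output <- function(x, ...) {
  cat(sprintf("<decoder_output> mean accuracy %.3f over %d folds (%s)\n",
              x$mean_accuracy, x$folds, x$feature))
  invisible(x)
}

#' Shuffled-label null distribution for a decoder
#'
#' Randomly permutes the binary behavior table `n_shuffles` times, reruns the
#' full cross-validated decoding on each permutation, and reports the null
#' accuracy distribution together with the real decoder's empirical p-value
#' `(1 + #{null >= real}) / (n_shuffles + 1)`.
#'
#' @inheritParams decode_cv
#' @param n_shuffles Number of label permutations (>= 1).
#' @return List with `real` (the un-shuffled `decoder_output`),
#'   `null_accuracies`, and `p_value`.
#' @export
shuffled_null <- function(tensor, n_shuffles = 100, folds = 10, seed = NULL,
                          feature_window = c(0, 5), flatten = FALSE) {
  if (n_shuffles < 1) stop("`n_shuffles` must be >= 1")
  real <- decode_cv(tensor, folds = folds, seed = seed,
                    feature_window = feature_window, flatten = flatten)
  null_acc <- vapply(seq_len(n_shuffles), function(s) {
    sh <- tensor
    sh$labels <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, s),
                           sample(tensor$labels))
    out <- suppressWarnings(
      decode_cv(sh, folds = folds,
                seed = if (is.null(seed)) NULL else derive_seed(seed, 7000 + s),
                feature_window = feature_window, flatten = flatten))
    out$mean_accuracy
  }, numeric(1))
  list(real = real, null_accuracies = null_acc,
       p_value = (1 + sum(null_acc >= real$mean_accuracy)) / (n_shuffles + 1))
}

#' Empirical CDF of decoder performance
#'
#' @param fold_accuracies Non-empty numeric vector of per-fold accuracies.
#' @return Data frame with columns `accuracy` (sorted unique values) and
#'   `cum_prob` (non-decreasing, ending at 1).
#' @export
performance_cdf <- function(fold_accuracies) {
  if (!length(fold_accuracies)) stop("empty accuracy list")
  acc <- sort(unique(fold_accuracies))
  data.frame(accuracy = acc,
             cum_prob = vapply(acc, function(a) mean(fold_accuracies <= a),
                               numeric(1)))
}

#' Peri-onset decoding time course
#'
#' At each time point of `time_grid` the population feature is each neuron's
#' average activity over the 1 s of data following that point; a fresh decoder
#' is trained and tested at every point with 5-fold cross-validation. A
#' shuffled-label control curve is computed the same way. When the grid covers
#' it, the area under the accuracy curve over data from 0-10 s after onset is
#' reported (`auc_0_10`, trapezoidal, accuracy x s).
#'
#' @param epochs_a,epochs_b `epoch_tensor`s for the two events.
#' @param neuron_subset Neuron ids to decode from (required, typically the
#'   activated set).
#' @param window_len Feature window length after each grid point, seconds
#'   (default 1).
#' @param folds CV folds at each time point (default 5).
#' @param time_grid Onset-relative times, seconds (default `seq(-10, 9, 0.5)`),
#'   strictly increasing; each window `[t, t + window_len)` must lie inside
#'   the epoch bounds.
#' @param n_shuffles Shuffled-label repeats averaged into the control curve at
#'   each time point (default 20).
#' @param seed Optional integer seed.
#' @return A `timecourse_result`: list with `times`, `accuracy`,
#'   `null_accuracy`, `auc_0_10`, `folds`, `window_len`.
#' @export
decode_timecourse <- function(epochs_a, epochs_b, neuron_subset,
                              window_len = 1, folds = 5,
                              time_grid = seq(-10, 9, by = 0.5),
                              n_shuffles = 20, seed = NULL) {
  if (is.unsorted(time_grid, strictly = TRUE)) {
    stop("`time_grid` must be strictly increasing")
  }
  tensor <- build_trial_tensor(epochs_a, epochs_b, neuron_subset)
  if (time_grid[1] < -tensor$pre_s ||
      time_grid[length(time_grid)] + window_len > tensor$post_s + 1e-9) {
    stop("window error: time_grid + window_len outside the epoch bounds")
  }
  acc <- numeric(length(time_grid))
  null_acc <- numeric(length(time_grid))
  for (i in seq_along(time_grid)) {
    w <- c(time_grid[i], time_grid[i] + window_len)
    sd_i <- if (is.null(seed)) NULL else derive_seed(seed, 100 + i)
    out <- suppressWarnings(decode_cv(tensor, folds = folds, seed = sd_i,
                                      feature_window = w))
    acc[i] <- out$mean_accuracy
    nulls <- vapply(seq_len(n_shuffles), function(s) {
      sh <- tensor
      sh$labels <- with_seed(if (is.null(sd_i)) NULL else derive_seed(sd_i, s),
                             sample(tensor$labels))
      suppressWarnings(decode_cv(sh, folds = folds,
                                 seed = if (is.null(sd_i)) NULL else
                                   derive_seed(sd_i, 5000 + s),
                                 feature_window = w))$mean_accuracy
    }, numeric(1))
    null_acc[i] <- mean(nulls)
  }
  in_auc <- time_grid >= 0 & time_grid + window_len <= 10 + 1e-9
  auc <- if (sum(in_auc) >= 2) pracma::trapz(time_grid[in_auc], acc[in_auc])
         else NA_real_
  structure(list(times = time_grid, accuracy = acc, null_accuracy = null_acc,
                 auc_0_10 = auc, folds = folds, window_len = window_len,
                 seed = seed),
            class = "timecourse_result")
}

#' Hyperplane-projection decoding of a continuous session
#'
#' Splits the session into two consecutive halves. On the first half a linear
#' maximum-margin classifier is trained to separate population activity frames
#' inside the labeled events from baseline frames drawn from a 5-s period
#' before each event. Every frame of the second half is then projected onto
#' the component normal to the decoder hyperplane, giving a continuous signed
#' prediction; runs of frames above `threshold` become predicted event
#' intervals, with runs shorter than `min_duration` discarded.
#'
#' @param traces Z-scored `trace_matrix` for the whole session.
#' @param events `event_table` with offsets for `label`.
#' @param label Event label to decode.
#' @param neuron_subset Neuron ids used as features (non-empty).
#' @param baseline_offset Onset-relative window (s) from which baseline
#'   training frames are taken (default `c(-5, 0)`).
#' @param split Fraction of the session used for training (default 0.5; the
#'   remainder is the test span).
#' @param threshold Projection threshold above which a frame is predicted to
#'   be inside an event (default 0, i.e. the hyperplane itself).
#' @param min_duration Minimum predicted-interval duration in seconds
#'   (default 0.5); suppresses single-frame flicker.
#' @param seed Unused randomness hook, kept for manifest provenance.
#' @return A `projection_result`: list with `projection` (data.frame `time_s`,
#'   `distance`), `predicted_intervals` (data.frame `start_s`, `end_s`),
#'   `threshold`, `train_span`, `test_span`, `weights`, `intercept`.
#' @export
projection_decoder <- function(traces, events, label, neuron_subset,
                               baseline_offset = c(-5, 0), split = 0.5,
                               threshold = 0, min_duration = 0.5, seed = NULL) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (split <= 0 || split >= 1) stop("`split` must be in (0, 1)")
  neuron_subset <- as.character(neuron_subset)
  if (!length(neuron_subset)) stop("`neuron_subset` must be non-empty")
  if (!all(neuron_subset %in% neuron_ids(traces))) {
    stop("unknown neurons in `neuron_subset`")
  }
  fs <- frame_rate(traces)
  n_frames <- ncol(traces)
  ev <- events[events$label == label, , drop = FALSE]
  if (!nrow(ev)) stop("no events with label \"", label, "\"")
  if (anyNA(ev$offset_s)) stop("events must carry offsets for projection decoding")
  split_frame <- as.integer(floor(n_frames * split))
  train_span <- c(0, split_frame / fs)
  test_span <- c(split_frame / fs, n_frames / fs)

  frames_of <- function(t0, t1) {          # session frames covering [t0, t1)
    f0 <- max(session_frame(t0, fs), 1L)
    f1 <- min(session_frame(t1, fs) - 1L, n_frames)
    if (f1 < f0) integer(0) else f0:f1
  }
  pos <- unlist(mapply(frames_of, ev$onset_s, ev$offset_s, SIMPLIFY = FALSE))
  neg <- unlist(mapply(frames_of, ev$onset_s + baseline_offset[1],
                       ev$onset_s + baseline_offset[2], SIMPLIFY = FALSE))
  neg <- setdiff(neg, pos)
  pos_tr <- pos[pos <= split_frame]
  neg_tr <- neg[neg <= split_frame]
  if (!length(pos_tr) || !length(pos[pos > split_frame])) {
    stop("split error: a session half contains no \"", label,
         "\" event; adjust `split`")
  }
  if (!length(neg_tr)) stop("split error: no baseline frames in the training half")

  x <- t(unclass(traces)[match(neuron_subset, neuron_ids(traces)), , drop = FALSE])
  tr_idx <- c(pos_tr, neg_tr)
  y_tr <- c(rep(1L, length(pos_tr)), rep(0L, length(neg_tr)))
  std <- standardizer(x[tr_idx, , drop = FALSE])
  fit <- fit_linear_svm(std$apply(x[tr_idx, , drop = FALSE]), y_tr)
  w_norm <- sqrt(sum(fit$w^2))

  te_idx <- (split_frame + 1L):n_frames
  dist <- (drop(std$apply(x[te_idx, , drop = FALSE]) %*% fit$w) + fit$b) / w_norm
  time_s <- (te_idx - 1L) / fs

  above <- is.finite(threshold) & dist > threshold
  runs <- rle(as.vector(above))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- data.frame(start_s = (te_idx[starts[runs$values]] - 1L) / fs,
                   end_s = te_idx[ends[runs$values]] / fs)
  iv <- iv[iv$end_s - iv$start_s >= min_duration, , drop = FALSE]
  rownames(iv) <- NULL

  structure(list(projection = data.frame(time_s = time_s, distance = dist),
                 predicted_intervals = iv, threshold = threshold,
                 train_span = train_span, test_span = test_span,
                 weights = fit$w, intercept = fit$b, label = label,
                 min_duration = min_duration, seed = seed),
            class = "projection_result")
}

#' Agreement between predicted and actual event intervals
#'
#' Rasterizes both interval sets onto the frame grid of a common span and
#' compares them frame-wise: overall accuracy (fraction of frames on which the
#' binary predicted and actual event indicators agree), intersection-over-
#' union of the event frames, and the per-event hit rate (fraction of actual
#' events overlapped by at least one predicted interval).
#'
#' @param predicted,actual Data frames with `start_s`, `end_s` columns.
#' @param span Numeric `c(t0, t1)` common evaluation span in seconds.
#' @param frame_rate Rasterization rate in Hz.
#' @return List with `accuracy`, `iou`, `hit_rate` (NA with a warning when
#'   there are no actual events), and `n_predicted`, `n_actual`.
#' @export
event_agreement <- function(predicted, actual, span, frame_rate) {
  grid <- seq(span[1] + 0.5 / frame_rate, span[2], by = 1 / frame_rate)
  rast <- function(iv) {
    out <- logical(length(grid))
    if (!is.null(iv) && nrow(iv)) {
      for (i in seq_len(nrow(iv))) {
        out <- out | (grid >= iv$start_s[i] & grid < iv$end_s[i])
      }
    }
    out
  }
  p <- rast(predicted); a <- rast(actual)
  iou <- if (any(p | a)) sum(p & a) / sum(p | a) else NA_real_
  hit_rate <- if (is.null(actual) || !nrow(actual)) {
    warning("no actual events: hit rate undefined")
    NA_real_
  } else {
    mean(vapply(seq_len(nrow(actual)), function(i) {
      any(p[grid >= actual$start_s[i] & grid < actual$end_s[i]])
    }, logical(1)))
  }
  list(accuracy = mean(p == a), iou = iou, hit_rate = hit_rate,
       n_predicted = if (is.null(predicted)) 0L else nrow(predicted),
       n_actual = if (is.null(actual)) 0L else nrow(actual))
}
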