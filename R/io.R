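#' Read and write trace matrices as CSV
#'
#' The on-disk layout is one row per neuron with frame times in the header.
#' Two comment lines (`# frame_rate=` and `# stage=`) precede the table so a
#' round-trip restores the full container; values are written with 15
#' significant digits (relative round-trip error well below 1e-12).
#'
#' @param tm A `trace_matrix`.
#' @param path File path.
#' @return `read_traces()` returns a `trace_matrix`; `write_traces()` returns
#'   `path` invisibly.
#' @export
write_traces <- function(tm, path) {
  stopifnot(inherits(tm, "trace_matrix"))
  con <- file(path, "w")
  writeLines(c(sprintf("# frame_rate=%.12g", frame_rate(tm)),
               sprintf("# stage=%s", trace_stage(tm))), con)
  close(con)
  m <- unclass(tm)
  dimnames(m) <- NULL
  dtm <- data.table::as.data.table(m)
  data.table::setnames(dtm, sprintf("t%.6f", frame_times(tm)))
  dt <- cbind(data.table::data.table(neuron_id = neuron_ids(tm)), dtm)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || !startsWith(header[1], "# frame_rate=") ||
      !startsWith(header[2], "# stage=")) {
    stop("malformed header in ", path,
         ": expected '# frame_rate=' and '# stage=' lines")
  }
  fs <- as.numeric(sub("# frame_rate=", "", header[1]))
  stage <- sub("# stage=", "", header[2])
  dt <- data.table::fread(path, skip = 2L, header = TRUE)
  if (!nrow(dt)) stop("empty input: no trace rows in ", path)
  ids <- as.character(dt[[1]])
  for (j in 2:ncol(dt)) {
    v <- dt[[j]]
    num <- if (is.numeric(v)) v else suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(num))
    if (length(bad)) {
      stop(sprintf("parse error in %s: non-numeric cell at row %d, column %d",
                   path, bad[1], j))
    }
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  trace_matrix(m, frame_rate = fs, neuron_ids = ids, stage = stage)
}

#' Read and write event tables as TSV
#'
#' Columns: `label`, `onset_s`, `offset_s` (empty where absent).
#'
#' @param events An `event_table`.
#' @param path File path.
#' @return `read_events()` returns an `event_table`; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path, sep = "\t")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("label", "onset_s")
  if (!all(need %in% names(dt))) {
    stop("malformed event table ", path, ": need columns label, onset_s")
  }
  event_table(dt$label, dt$onset_s,
              if ("offset_s" %in% names(dt)) dt$offset_s else NA_real_)
}

#' Read a cross-session cell-correspondence table
#'
#' @param path TSV with columns `id_a`, `id_b` (the output of an external
#'   spatial-footprint registration step).
#' @return Data frame with character columns `id_a`, `id_b`.
#' @export
read_mapping <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("id_a", "id_b") %in% names(dt))) {
    stop("malformed mapping ", path, ": need columns id_a, id_b")
  }
  as.data.frame(dt)
}

#' Build a run configuration
#'
#' Collects every stage parameter with defaults matching the pipeline's
#' standard analysis choices: 10 s pre/post epochs, baseline `[-5, 0)` and
#' event `[0, 5)` windows, 1000 permutations at alpha 0.05 with the 0.2 z
#' magnitude rule, SRI cut-offs at +/-0.2, 10-fold decoding CV with 100 label
#' shuffles, 5-fold 1-s-window decoding time courses.
#'
#' @param traces_path,events_path Input files (required for [run_pipeline()]).
#' @param label_a,label_b The two event labels to analyze and decode.
#' @param mapping_path Optional correspondence TSV.
#' @param outdir Output directory.
#' @param overrides Named list overriding any default parameter.
#' @return A `run_config` list.
#' @export
run_config <- function(traces_path = NULL, events_path = NULL,
                       label_a = "A", label_b = "B",
                       mapping_path = NULL, outdir = NULL,
                       overrides = list()) {
  cfg <- list(traces_path = traces_path, events_path = events_path,
              mapping_path = mapping_path, outdir = outdir,
              label_a = label_a, label_b = label_b,
              pre_s = 10, post_s = 10,
              baseline_window = c(-5, 0), event_window = c(0, 5),
              n_perm = 1000, alpha = 0.05, z_threshold = 0.2,
              sri_threshold = 0.2,
              folds = 10, n_shuffles = 100,
              timecourse_folds = 5, timecourse_window = 1,
              time_grid = seq(-10, 9, by = 0.5),
              seed = 1, verbose = FALSE)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config parameter(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] parameters.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fixed <- intersect(names(y), c("traces_path", "events_path", "mapping_path",
                                 "outdir", "label_a", "label_b"))
  do.call(run_config, c(y[fixed], list(overrides = y[setdiff(names(y), fixed)])))
}

#' Run the full peri-event ensemble pipeline
#'
#' Mirrors the standard analysis order: z-score the session traces, extract
#' peri-event epochs for the two labels, detect activated neurons in each by
#' permutation test, classify selectivity by SRI across the two events, then
#' decode the two events from the joint activated ensemble (cross-validated
#' accuracy, shuffled-label null, performance CDF). Every output is written
#' under `outdir` together with a manifest recording all parameters, seeds,
#' package version and exclusion counts, so results are reproducible from the
#' manifest alone.
#'
#' @param config A `run_config` with `traces_path`, `events_path`, `outdir`
#'   set.
#' @return Invisibly, a list with `activation_a`, `activation_b`,
#'   `selectivity`, `decoding`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (need in c("traces_path", "events_path", "outdir")) {
    if (is.null(config[[need]])) stop("config validation: `", need, "` is required")
  }
  if (!file.exists(config$traces_path)) {
    stop("config validation: traces_path does not exist: ", config$traces_path)
  }
  if (!file.exists(config$events_path)) {
    stop("config validation: events_path does not exist: ", config$events_path)
  }
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  traces <- stage("read", read_traces(config$traces_path))
  events <- stage("read", read_events(config$events_path))
  z <- stage("zscore", {
    if (trace_stage(traces) == "raw") traces <- compute_dff(traces)
    if (trace_stage(traces) != "zscored") zscore_traces(traces) else traces
  })
  say("z-scored ", nrow(z), " neurons")

  ep_a <- stage("epochs", extract_epochs(z, events, config$label_a,
                                         config$pre_s, config$post_s))
  ep_b <- stage("epochs", extract_epochs(z, events, config$label_b,
                                         config$pre_s, config$post_s))
  act_a <- stage("detect", detect_activated(
    ep_a, as_window(config$baseline_window), as_window(config$event_window),
    n_perm = config$n_perm, alpha = config$alpha,
    z_threshold = config$z_threshold, seed = derive_seed(config$seed, 1)))
  act_b <- stage("detect", detect_activated(
    ep_b, as_window(config$baseline_window), as_window(config$event_window),
    n_perm = config$n_perm, alpha = config$alpha,
    z_threshold = config$z_threshold, seed = derive_seed(config$seed, 2)))
  say(sum(act_a$activated), " / ", sum(act_b$activated),
      " neurons activated for ", config$label_a, " / ", config$label_b)

  resp_a <- stats::setNames(act_a$response, act_a$neuron)
  resp_b <- stats::setNames(act_b$response, act_b$neuron)
  sri <- stage("sri", compute_sri(resp_a, resp_b))
  selectivity <- data.frame(neuron = act_a$neuron, sri = sri,
                            category = classify_selectivity(
                              sri, config$sri_threshold),
                            stringsAsFactors = FALSE)

  activated <- union(act_a$neuron[act_a$activated],
                     act_b$neuron[act_b$activated])
  decoding <- NULL
  if (length(activated) >= 1) {
    decoding <- stage("decode", {
      tensor <- build_trial_tensor(ep_a, ep_b, activated)
      nl <- shuffled_null(tensor, n_shuffles = config$n_shuffles,
                          folds = config$folds,
                          seed = derive_seed(config$seed, 3),
                          feature_window = config$event_window)
      list(mean_accuracy = nl$real$mean_accuracy,
           fold_accuracies = nl$real$fold_accuracies,
           null_accuracies = nl$null_accuracies, p_value = nl$p_value,
           cdf = performance_cdf(nl$real$fold_accuracies),
           n_neurons = length(activated))
    })
    say("decoder accuracy ", round(decoding$mean_accuracy, 3),
        " (shuffled-null p = ", signif(decoding$p_value, 3), ")")
  }

  utils::write.table(act_a, file.path(config$outdir, "activation_a.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(act_b, file.path(config$outdir, "activation_b.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(selectivity, file.path(config$outdir, "selectivity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(decoding)) {
    jsonlite::write_json(decoding, file.path(config$outdir, "decoding.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "periens",
    version = as.character(utils::packageVersion("periens")),
    config = config[setdiff(names(config), "verbose")],
    seeds = list(master = config$seed,
                 detect_a = derive_seed(config$seed, 1),
                 detect_b = derive_seed(config$seed, 2),
                 decode = derive_seed(config$seed, 3)),
    exclusions = list(zero_sd_neurons = attr(z, "excluded"),
                      epochs_a_excluded = attr(ep_a, "n_excluded"),
                      epochs_b_excluded = attr(ep_b, "n_excluded")),
    counts = list(neurons = nrow(z),
                  activated_a = sum(act_a$activated),
                  activated_b = sum(act_b$activated)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(activation_a = act_a, activation_b = act_b,
                 selectivity = selectivity, decoding = decoding,
                 manifest = manifest))
}

#' Write synthetic ground truth to JSON
#'
#' @param gt The `ground_truth` element of [generate_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(
    list(seed = gt$seed,
         responsive_map = gt$responsive_map,
         amplitudes = as.data.frame(gt$amplitudes)),
    path, auto_unbox = TRUE, digits = NA, null = "list")
  invisible(path)
}
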