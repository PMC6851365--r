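#' Pipeline run configuration
#'
#' Bundles the knobs of the end-to-end pipeline. The defaults are the
#' reference operating point: 1 FPS sampling, 299x168 input frames, a
#' 5-frame trailing moving average, and last-detection phase ends.
#'
#' @param resolution `(width, height)` of classifier input frames.
#' @param rate_fps frame sampling rate.
#' @param window_len smoothing window length (frames).
#' @param end_rule `"last_detection"` or `"pre_next_phase"`.
#' @param classifier_kind `"confusion_model"` or `"cnn"`.
#' @param seed integer master seed for stochastic stages, or `NULL`.
#' @return A `run_config` list.
#' @export
run_config <- function(resolution = c(299L, 168L), rate_fps = 1,
                       window_len = 5L,
                       end_rule = c("last_detection", "pre_next_phase"),
                       classifier_kind = c("confusion_model", "cnn"),
                       seed = NULL) {
  end_rule <- match.arg(end_rule)
  classifier_kind <- match.arg(classifier_kind)
  stopifnot(length(resolution) == 2L, rate_fps > 0, window_len >= 1L)
  structure(list(resolution = as.integer(resolution), rate_fps = rate_fps,
                 window_len = as.integer(window_len), end_rule = end_rule,
                 classifier_kind = classifier_kind, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for the writer).
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  run_config(resolution = v$resolution, rate_fps = v$rate_fps,
             window_len = v$window_len, end_rule = v$end_rule,
             classifier_kind = v$classifier_kind, seed = v$seed)
}

# stable content hash (32-bit polynomial rolling hash) of the config YAML
config_hash <- function(config) {
  s <- utf8ToInt(yaml::as.yaml(unclass(config)))
  h <- 0
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the segmentation pipeline end to end
#'
#' Composes the stages ingest -> classify -> smooth -> extract (-> evaluate
#' when ground truth is supplied). The input may enter at any stage: a video
#' source or frame directory (ingested first), a labeled `frame_stream`
#' (classified first), or a score stream `data.frame` (smoothed directly).
#' All intermediate artifacts are persisted when `out_dir` is given, so any
#' stage can be rerun in isolation, together with a manifest recording the
#' configuration, its hash and the seed.
#'
#' @param input video source, `frame_stream`, or score stream.
#' @param config a [run_config()].
#' @param truth optional [phase_timeline()] ground truth; enables the
#'   evaluation stage (and provides frame labels for the confusion-model
#'   classifier).
#' @param classifier optional classifier object; defaults to a
#'   [confusion_classifier()] when `config$classifier_kind` is
#'   `"confusion_model"`.
#' @param out_dir optional output directory for artifacts
#'   (`scores.csv`, `decisions.csv`, `result.json`, `report.json`,
#'   `manifest.json`).
#' @return List with `scores`, `decisions`, `result` and, when truth was
#'   supplied, `confusion` and `boundary` reports.
#' @export
run_pipeline <- function(input, config = run_config(), truth = NULL,
                         classifier = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- tic() - t0
    r
  }

  frames <- NULL
  scores <- NULL
  if (is.data.frame(input)) {
    scores <- validate_score_stream(input)
  } else if (inherits(input, "frame_stream")) {
    frames <- input
  } else {
    frames <- stage("ingest", extract_frames(input, config$rate_fps,
                                             config$resolution))
  }
  if (is.null(scores)) {
    if (is.null(classifier)) {
      if (config$classifier_kind == "cnn")
        stop("classifier_kind 'cnn' needs a trained classifier object",
             call. = FALSE)
      classifier <- confusion_classifier()
    }
    if (inherits(classifier, "confusion_classifier") &&
        is.null(frames[[1]]$label)) {
      if (is.null(truth))
        stop("confusion-model classification needs labeled frames or truth",
             call. = FALSE)
      labs <- frame_labels(frames, truth)
      for (i in seq_along(frames)) frames[[i]]$label <- labs[i]
    }
    scores <- stage("classify",
      if (inherits(classifier, "confusion_classifier"))
        classify_stream(classifier, frames, seed = config$seed)
      else classify_stream(classifier, frames))
  }
  decisions <- stage("smooth", smooth_stream(scores, config$window_len))
  result <- stage("extract", extract_boundaries(decisions, config$end_rule))

  out <- list(scores = scores, decisions = decisions, result = result,
              timings = timings)
  if (!is.null(truth)) {
    out$confusion <- stage("evaluate", frame_confusion(decisions, truth))
    out$boundary <- boundary_errors(list(result), list(truth))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scores(scores, file.path(out_dir, "scores.csv"))
    write_decisions(decisions, file.path(out_dir, "decisions.csv"))
    write_segmentation(result, file.path(out_dir, "result.json"))
    if (!is.null(out$confusion)) {
      rep <- list(per_class_rate = as.list(out$confusion$per_class_rate),
                  weighted_mean_rate = out$confusion$weighted_mean_rate,
                  counts = out$confusion$counts,
                  boundary_mae = as.list(out$boundary$mae),
                  overall_mean_mae = out$boundary$overall_mean_mae)
      jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    manifest <- list(config = unclass(config),
                     config_hash = config_hash(config),
                     seed = config$seed,
                     timings_s = as.list(round(unlist(timings), 3)),
                     package_version = as.character(
                       utils::packageVersion("phacoseg")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Evaluate a cohort of score streams against their truths
#'
#' Runs smoothing and boundary extraction on every surgery of a cohort and
#' pools the per-frame confusion and boundary errors, mirroring how a
#' held-out test set is scored.
#'
#' @param truths list of [phase_timeline()].
#' @param scores list of score streams, paired with `truths`.
#' @param config a [run_config()].
#' @param confusion_window window length used for the per-frame confusion
#'   report; defaults to `config$window_len`. (Per-frame classifier rates
#'   correspond to window 1, i.e. no smoothing.)
#' @return List with pooled `confusion` (a `confusion_report`), `boundary`
#'   (a `boundary_error_report`) and per-surgery `results`.
#' @export
evaluate_cohort <- function(truths, scores, config = run_config(),
                            confusion_window = NULL) {
  stopifnot(length(truths) == length(scores), length(truths) >= 1L)
  cw <- confusion_window %||% config$window_len
  results <- vector("list", length(truths))
  confs <- vector("list", length(truths))
  for (i in seq_along(truths)) {
    dec <- smooth_stream(scores[[i]], config$window_len)
    results[[i]] <- extract_boundaries(dec, config$end_rule)
    cdec <- if (cw == config$window_len) dec else
      smooth_stream(scores[[i]], cw)
    confs[[i]] <- frame_confusion(cdec, truths[[i]])
  }
  list(confusion = pool_confusion(confs),
       boundary = boundary_errors(results, truths),
       results = results)
}
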