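#' Per-frame confusion report against a ground-truth timeline
#'
#' Scores every decided frame against the true per-second label implied by
#' the annotation (closed intervals; gaps are OTHER). Warm-up seconds — those
#' before the smoothing window fills — carry no decision and are excluded by
#' construction. Per-class correct-response rate is
#' `100 * counts[r, r] / sum(counts[r, ])`, and the weighted mean rate is
#' `100 * trace / total`, i.e. the frame-count-weighted mean of the
#' per-class rates.
#'
#' @param decisions a decision stream from [smooth_stream()].
#' @param truth a [phase_timeline()] covering the decided seconds.
#' @return A `confusion_report`: list with `counts` (3x3 integer matrix,
#'   rows = truth, columns = decided), `per_class_rate` (percent),
#'   `weighted_mean_rate` (percent), `n_frames`.
#' @export
frame_confusion <- function(decisions, truth) {
  if (!is.data.frame(decisions) || nrow(decisions) == 0L)
    stop("no decided frames to score", call. = FALSE)
  dur <- max(max(decisions$time_s) + 1L, timeline_duration(truth))
  labels <- labels_from_timeline(truth, dur)
  true_lab <- labels[decisions$time_s + 1L]
  lv <- phase_labels()
  counts <- table(factor(true_lab, levels = lv),
                  factor(decisions$decided_phase, levels = lv))
  counts <- matrix(as.integer(counts), 3L, 3L,
                   dimnames = list(truth = lv, decided = lv))
  confusion_report(counts)
}

confusion_report <- function(counts) {
  row_n <- rowSums(counts)
  rate <- ifelse(row_n > 0, 100 * diag(counts) / row_n, NA_real_)
  names(rate) <- rownames(counts)
  structure(list(counts = counts, per_class_rate = rate,
                 weighted_mean_rate = 100 * sum(diag(counts)) / sum(counts),
                 n_frames = sum(counts)),
            class = "confusion_report")
}

#' Pool several confusion reports
#'
#' Sums the count matrices of per-surgery reports and recomputes the rates,
#' so a cohort-level report weights each frame equally.
#'
#' @param reports list of `confusion_report` objects.
#' @return A pooled `confusion_report`.
#' @export
pool_confusion <- function(reports) {
  stopifnot(length(reports) >= 1L)
  counts <- Reduce(`+`, lapply(reports, function(r) r$counts))
  confusion_report(counts)
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Per-frame confusion (", x$n_frames, " decided frames)\n", sep = "")
  print(x$counts)
  cat("Correct response rate [%]:",
      paste(sprintf("%s %.1f", names(x$per_class_rate), x$per_class_rate),
            collapse = ", "), "\n")
  cat(sprintf("Mean (frame-weighted): %.1f%%\n", x$weighted_mean_rate))
  invisible(x)
}

boundary_names <- function()
  c("ccc_start", "ccc_end", "nuclear_start", "nuclear_end")

# per-surgery absolute boundary errors (seconds); NA where undetected
boundary_abs_errors <- function(result, truth) {
  stopifnot(inherits(result, "segmentation_result"),
            inherits(truth, "phase_timeline"))
  tru <- c(ccc_start = interval_of(truth, "CCC")[1],
           ccc_end = interval_of(truth, "CCC")[2],
           nuclear_start = interval_of(truth, "NUCLEAR")[1],
           nuclear_end = interval_of(truth, "NUCLEAR")[2])
  det <- c(result$ccc_start_s, result$ccc_end_s,
           result$nuclear_start_s, result$nuclear_end_s)
  err <- abs(det - tru)
  names(err) <- boundary_names()
  err
}

interval_of <- function(timeline, lab) {
  r <- timeline[timeline$phase == lab, , drop = FALSE]
  if (nrow(r) == 0L) c(NA_integer_, NA_integer_)
  else c(r$start_s[1], r$end_s[1])
}

#' Boundary-error report over a cohort
#'
#' For each surgery and each of the four phase boundaries (CCC start/end,
#' nuclear-extraction start/end), the absolute error in seconds between the
#' detected and annotated time. Undetected boundaries are excluded from the
#' means and tallied in `n_missing`. The overall figure is the unweighted
#' mean of the four per-boundary mean absolute errors.
#'
#' @param results list of `segmentation_result` objects (from
#'   [extract_boundaries()]), named or ordered to pair with `truths`.
#' @param truths list of [phase_timeline()] ground truths.
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1).
#' @return A `boundary_error_report`: list with `abs_errors` (surgeries x 4
#'   matrix), `mae`, `sd` (length-4, seconds), `overall_mean_mae`,
#'   `n_missing`.
#' @export
boundary_errors <- function(results, truths,
                            sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(results) != length(truths))
    stop("results and truths must have equal length", call. = FALSE)
  results <- pair_by_source(results, truths)
  errs <- t(vapply(seq_along(results),
                   function(i) boundary_abs_errors(results[[i]], truths[[i]]),
                   numeric(4)))
  colnames(errs) <- boundary_names()
  rownames(errs) <- vapply(truths, function(tr)
    attr(tr, "source_id") %||% "", character(1))
  mae <- colMeans(errs, na.rm = TRUE)
  sdv <- apply(errs, 2L, function(e) {
    e <- e[!is.na(e)]
    if (length(e) == 0L) return(NA_real_)
    if (sd_type == "population") sqrt(mean((e - mean(e))^2)) else stats::sd(e)
  })
  structure(list(abs_errors = errs, mae = mae, sd = sdv,
                 overall_mean_mae = mean(mae),
                 n_missing = colSums(is.na(errs)), sd_type = sd_type),
            class = "boundary_error_report")
}

# align results to truths by source_id when both sides carry ids
pair_by_source <- function(results, truths) {
  tid <- vapply(truths, function(tr) attr(tr, "source_id") %||% NA_character_,
                character(1))
  rid <- vapply(results, function(r) r$source_id %||% NA_character_,
                character(1))
  if (anyNA(tid) || anyNA(rid)) return(results)  # positional pairing
  m <- match(tid, rid)
  if (anyNA(m))
    stop("unmatched source_id(s): ", paste(tid[is.na(m)], collapse = ", "),
         call. = FALSE)
  results[m]
}

#' @export
print.boundary_error_report <- function(x, ...) {
  cat("Boundary absolute errors over", nrow(x$abs_errors), "surgeries\n")
  tab <- rbind(`MAE [s]` = x$mae, `SD [s]` = x$sd, missing = x$n_missing)
  print(round(tab, 2))
  cat(sprintf("Overall mean MAE: %.2f s\n", x$overall_mean_mae))
  invisible(x)
}

#' Timeline strip data for truth-vs-determination plots
#'
#' Builds the data behind the two aligned color strips conventionally used
#' to visualize phase recognition: per elapsed second, the annotated phase
#' and (when decisions are supplied) the decided phase. Warm-up seconds and
#' seconds outside the decision range are `NA` in the determination row.
#'
#' @param truth a [phase_timeline()].
#' @param decisions optional decision stream.
#' @param out optional CSV path; when given, the strip table is written
#'   there.
#' @return A `data.frame` with columns `time_s`, `truth` and (if decisions
#'   were supplied) `determination`.
#' @export
timeline_strip <- function(truth, decisions = NULL, out = NULL) {
  dur <- timeline_duration(truth)
  if (!is.null(decisions) && nrow(decisions) > 0L)
    dur <- max(dur, max(decisions$time_s) + 1L)
  strip <- data.frame(time_s = 0:(dur - 1L),
                      truth = labels_from_timeline(truth, dur),
                      stringsAsFactors = FALSE)
  if (!is.null(decisions)) {
    det <- rep(NA_character_, dur)
    det[decisions$time_s + 1L] <- decisions$decided_phase
    strip$determination <- det
  }
  if (!is.null(out)) utils::write.csv(strip, out, row.names = FALSE,
                                      quote = FALSE)
  strip
}

#' Plot a truth-vs-determination timeline strip
#'
#' Renders the strip from [timeline_strip()] with the conventional colors
#' (CCC red, nuclear extraction blue, others green). Requires ggplot2.
#'
#' @param strip output of [timeline_strip()].
#' @return A ggplot object.
#' @export
plot_timeline_strip <- function(strip) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  rows <- intersect(c("truth", "determination"), names(strip))
  long <- do.call(rbind, lapply(rows, function(r)
    data.frame(time_s = strip$time_s, row = r, phase = strip[[r]])))
  long$row <- factor(long$row, levels = rev(rows))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$row,
                                     fill = .data$phase)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(
      values = c(CCC = "#d62728", NUCLEAR = "#1f77b4", OTHER = "#2ca02c"),
      na.value = "grey85") +
    ggplot2::labs(x = "elapsed time [s]", y = NULL, fill = "phase") +
    ggplot2::theme_minimal()
}

#' Long-format boundary errors for boxplots
#'
#' @param report a `boundary_error_report`.
#' @return `data.frame` with columns `boundary`, `surgery_id`,
#'   `abs_error_s` (one row per detected boundary per surgery).
#' @export
boundary_error_long <- function(report) {
  stopifnot(inherits(report, "boundary_error_report"))
  e <- report$abs_errors
  long <- data.frame(boundary = rep(colnames(e), each = nrow(e)),
                     surgery_id = rep(rownames(e), times = ncol(e)),
                     abs_error_s = as.vector(e))
  long[!is.na(long$abs_error_s), , drop = FALSE]
}
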