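#' Trailing moving-average smoothing of a score stream
#'
#' The real-time temporal filter at the heart of the pipeline: for each
#' second `i`, the smoothed score of class `j` is the arithmetic mean of the
#' last `window_len` per-frame scores of that class,
#' \deqn{Ave_i^j = \frac{1}{w}\sum_{k=i-w+1}^{i} eval_k^j,}
#' and the decided phase is the argmax over the three smoothed scores.
#' Decisions are emitted only once the window is full (the first
#' `window_len - 1` frames are warm-up), so the decision at second `i`
#' depends on seconds `i - window_len + 1 .. i` only — the filter is causal
#' and suitable for intra-operative use.
#'
#' The implementation is streaming: internal state is exactly the last
#' `window_len` score triples plus a running sum. [smooth_stream()] is the
#' batch convenience wrapper; [smoother_new()]/[smoother_push()] expose the
#' frame-at-a-time interface.
#'
#' @param scores a score stream: `data.frame` with columns
#'   `time_s, score_ccc, score_nuclear, score_other`, time-ordered with
#'   contiguous seconds.
#' @param window_len window length in frames (seconds at 1 FPS); default 5.
#' @return A decision stream: `data.frame` with columns
#'   `time_s, ave_ccc, ave_nuclear, ave_other, decided_phase`, one row per
#'   second from the `window_len`-th input frame on.
#' @seealso [decide_phase()], [extract_boundaries()]
#' @export
#' @examples
#' s <- data.frame(time_s = 0:9, score_ccc = 1, score_nuclear = 0,
#'                 score_other = 0)
#' smooth_stream(s, window_len = 5)
smooth_stream <- function(scores, window_len = 5L) {
  scores <- validate_score_stream(scores)
  window_len <- as.integer(window_len)
  if (is.na(window_len) || window_len < 1L)
    stop("window_len must be a positive integer", call. = FALSE)
  n <- nrow(scores)
  if (n < window_len) {
    warning("stream shorter than window_len; no decisions emitted")
    return(empty_decision_stream())
  }
  sm <- smoother_new(window_len)
  out_t <- integer(n - window_len + 1L)
  out_ave <- matrix(0, n - window_len + 1L, 3L)
  out_ph <- character(n - window_len + 1L)
  k <- 0L
  svals <- as.matrix(scores[, score_cols()])
  for (i in seq_len(n)) {
    sm <- smoother_push(sm, scores$time_s[i], svals[i, ])
    if (!is.null(sm$decision)) {
      k <- k + 1L
      out_t[k] <- sm$decision$time_s
      out_ave[k, ] <- sm$decision$ave
      out_ph[k] <- sm$decision$decided_phase
    }
  }
  d <- data.frame(time_s = out_t, ave_ccc = out_ave[, 1],
                  ave_nuclear = out_ave[, 2], ave_other = out_ave[, 3],
                  decided_phase = out_ph, stringsAsFactors = FALSE)
  attr(d, "window_len") <- window_len
  attr(d, "source_id") <- attr(scores, "source_id")
  class(d) <- c("decision_stream", "data.frame")
  d
}

#' Streaming smoother state
#'
#' @param window_len window length in frames.
#' @return An opaque smoother state for [smoother_push()].
#' @rdname smooth_stream
#' @export
smoother_new <- function(window_len = 5L) {
  window_len <- as.integer(window_len)
  if (is.na(window_len) || window_len < 1L)
    stop("window_len must be a positive integer", call. = FALSE)
  list(window_len = window_len, buf = matrix(numeric(0), 0, 3),
       times = integer(0), decision = NULL)
}

#' Push one score triple into a streaming smoother
#'
#' @param state smoother state from [smoother_new()] or a previous push.
#' @param time_s integer second of the incoming frame.
#' @param scores numeric length-3 score triple `(ccc, nuclear, other)`.
#' @return Updated state; `state$decision` is `NULL` during warm-up and
#'   otherwise a list `(time_s, ave, decided_phase)` for the pushed frame.
#' @rdname smooth_stream
#' @export
smoother_push <- function(state, time_s, scores) {
  stopifnot(length(scores) == 3L)
  if (length(state$times) > 0L && time_s != state$times[length(state$times)] + 1L)
    stop("scores must arrive at contiguous, increasing seconds", call. = FALSE)
  buf <- rbind(state$buf, as.numeric(scores))
  times <- c(state$times, as.integer(time_s))
  w <- state$window_len
  if (nrow(buf) > w) {  # state is exactly the trailing window
    buf <- buf[-1L, , drop = FALSE]
    times <- times[-1L]
  }
  state$buf <- buf
  state$times <- times
  if (nrow(buf) == w) {
    ave <- colMeans(buf)
    state$decision <- list(time_s = times[w], ave = ave,
                           decided_phase = decide_phase(ave))
  } else state$decision <- NULL
  state
}

#' Argmax phase decision with a fixed tie-break
#'
#' Returns the phase whose (smoothed) score is maximal. Ties are broken by
#' the fixed class order CCC, NUCLEAR, OTHER (lowest index wins), so the
#' decision is deterministic.
#'
#' @param ave numeric length-3 vector of class scores in the order
#'   `(CCC, NUCLEAR, OTHER)`.
#' @return One of `phase_labels()`.
#' @export
#' @examples
#' decide_phase(c(0.4, 0.4, 0.2))  # tie -> "CCC"
decide_phase <- function(ave) {
  if (length(ave) != 3L) stop("ave must have length 3", call. = FALSE)
  if (any(is.na(ave)) || any(!is.finite(ave)))
    stop("ave contains NaN/NA/Inf", call. = FALSE)
  phase_labels()[which.max(ave)]  # which.max takes the first maximum
}

#' Extract phase start and end times from a decision stream
#'
#' The start time of a phase is the second at which a frame is first decided
#' as that phase. Two end rules are provided:
#' \describe{
#'   \item{`last_detection`}{the end time is the second at which the phase is
#'     last decided (the default; well-defined because CCC and nuclear
#'     extraction are separated by other maneuvers in real surgeries).}
#'   \item{`pre_next_phase`}{the CCC end time is the second immediately
#'     before the first NUCLEAR decision; the NUCLEAR end time is the second
#'     immediately before the first decided-phase change after the NUCLEAR
#'     start.}
#' }
#' A phase never decided yields `NA` for both of its times. Fragmented
#' detections are spanned: start is the first and end the last detection,
#' across any gaps.
#'
#' @param decisions a decision stream from [smooth_stream()].
#' @param end_rule `"last_detection"` or `"pre_next_phase"`.
#' @return A `segmentation_result`: list with `ccc_start_s`, `ccc_end_s`,
#'   `nuclear_start_s`, `nuclear_end_s` (integer seconds or `NA`),
#'   `end_rule`, `window_len` (if known) and the `decisions` themselves.
#' @export
extract_boundaries <- function(decisions,
                               end_rule = c("last_detection", "pre_next_phase")) {
  end_rule <- match.arg(end_rule)
  if (!is.data.frame(decisions) || nrow(decisions) == 0L)
    stop("decisions must be a non-empty decision stream", call. = FALSE)
  ph <- decisions$decided_phase
  t <- decisions$time_s

  first_t <- function(lab) {
    i <- which(ph == lab)
    if (length(i) == 0L) NA_integer_ else t[i[1L]]
  }
  last_t <- function(lab) {
    i <- which(ph == lab)
    if (length(i) == 0L) NA_integer_ else t[i[length(i)]]
  }

  ccc_start <- first_t("CCC")
  nuc_start <- first_t("NUCLEAR")
  if (end_rule == "last_detection") {
    ccc_end <- last_t("CCC")
    nuc_end <- last_t("NUCLEAR")
  } else {
    ccc_end <- if (is.na(ccc_start)) NA_integer_
      else if (!is.na(nuc_start)) nuc_start - 1L
      else last_t("CCC")
    nuc_end <- NA_integer_
    if (!is.na(nuc_start)) {
      after <- which(t > nuc_start & ph != "NUCLEAR")
      nuc_end <- if (length(after) > 0L) t[after[1L]] - 1L else t[length(t)]
    }
  }
  res <- list(ccc_start_s = ccc_start, ccc_end_s = ccc_end,
              nuclear_start_s = nuc_start, nuclear_end_s = nuc_end,
              end_rule = end_rule,
              window_len = attr(decisions, "window_len"),
              source_id = attr(decisions, "source_id"),
              decisions = decisions)
  class(res) <- "segmentation_result"
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "missing", paste0(v, " s"))
  cat("Segmentation result (end rule:", x$end_rule, ")\n")
  cat("  CCC:    ", fmt(x$ccc_start_s), "->", fmt(x$ccc_end_s), "\n")
  cat("  NUCLEAR:", fmt(x$nuclear_start_s), "->", fmt(x$nuclear_end_s), "\n")
  invisible(x)
}

empty_decision_stream <- function() {
  d <- data.frame(time_s = integer(0), ave_ccc = numeric(0),
                  ave_nuclear = numeric(0), ave_other = numeric(0),
                  decided_phase = character(0), stringsAsFactors = FALSE)
  class(d) <- c("decision_stream", "data.frame")
  d
}

validate_score_stream <- function(scores) {
  need <- c("time_s", score_cols())
  if (!is.data.frame(scores) || !all(need %in% names(scores)))
    stop("score stream needs columns time_s,", paste(score_cols(), collapse = ","),
         call. = FALSE)
  if (nrow(scores) > 1L && any(diff(scores$time_s) != 1L))
    stop("score stream must be time-ordered with contiguous seconds",
         call. = FALSE)
  scores
}
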