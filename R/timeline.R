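#' Construct a phase timeline
#'
#' A phase timeline is the ground-truth (or detected) segmentation of one
#' surgery: for each labeled phase, its start and end time in integer seconds
#' from video start. Intervals are closed: frame `t` belongs to phase `L`
#' iff `start_s <= t <= end_s`; seconds covered by no row are `OTHER`.
#'
#' Validation enforces the anatomy of phacoemulsification: the capsulorrhexis
#' (CCC) interval must precede and not overlap the nuclear-extraction
#' interval, and every interval must satisfy `start_s < end_s`.
#'
#' @param phase character vector of phase labels (see [phase_labels()]).
#' @param start_s,end_s integer seconds, 0-based from video start, closed
#'   interval.
#' @param source_id surgery identifier string attached as an attribute.
#' @return A `phase_timeline`: a `data.frame` with columns
#'   `phase`, `start_s`, `end_s`, ordered by `start_s`.
#' @export
#' @examples
#' phase_timeline(c("CCC", "NUCLEAR"), c(60, 130), c(100, 260))
phase_timeline <- function(phase, start_s, end_s, source_id = "surgery") {
  phase <- as_phase_label(phase)
  start_s <- as.integer(start_s)
  end_s <- as.integer(end_s)
  stopifnot(length(phase) == length(start_s), length(phase) == length(end_s))
  tl <- data.frame(phase = phase, start_s = start_s, end_s = end_s,
                   stringsAsFactors = FALSE)
  tl <- tl[order(tl$start_s), , drop = FALSE]
  rownames(tl) <- NULL
  attr(tl, "source_id") <- source_id
  class(tl) <- c("phase_timeline", "data.frame")
  validate_timeline(tl)
  tl
}

validate_timeline <- function(tl) {
  if (any(is.na(tl$start_s)) || any(is.na(tl$end_s)))
    stop("timeline has missing start/end times", call. = FALSE)
  if (any(tl$start_s < 0))
    stop("timeline start times must be non-negative", call. = FALSE)
  bad <- tl$start_s >= tl$end_s
  if (any(bad))
    stop("invalid interval(s): start_s must be < end_s (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  ccc <- tl[tl$phase == "CCC", , drop = FALSE]
  nuc <- tl[tl$phase == "NUCLEAR", , drop = FALSE]
  if (nrow(ccc) > 1L || nrow(nuc) > 1L)
    stop("at most one CCC and one NUCLEAR interval per surgery", call. = FALSE)
  if (nrow(ccc) == 1L && nrow(nuc) == 1L) {
    if (ccc$start_s[1] <= nuc$end_s[1] && nuc$start_s[1] <= ccc$end_s[1])
      stop("CCC and NUCLEAR intervals overlap", call. = FALSE)
    if (ccc$start_s[1] >= nuc$start_s[1])
      stop("CCC interval must precede the NUCLEAR interval", call. = FALSE)
  }
  invisible(tl)
}

#' Read a phase annotation CSV
#'
#' Reads the annotation format produced by an annotating ophthalmologist (or
#' by [write_annotation()]): a CSV with header `phase,start_s,end_s`, times
#' as 0-based integer seconds, intervals closed.
#'
#' @param path path to the CSV file.
#' @param source_id surgery identifier; defaults to the file's base name.
#' @return A validated [phase_timeline()].
#' @export
load_annotation <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "start_s", "end_s")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns phase,start_s,end_s", call. = FALSE)
  if (is.null(source_id))
    source_id <- sub("\\.[^.]*$", "", basename(path))
  phase_timeline(df$phase, df$start_s, df$end_s, source_id = source_id)
}

#' Write a phase timeline as an annotation CSV
#'
#' @param timeline a [phase_timeline()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(timeline, path) {
  stopifnot(inherits(timeline, "phase_timeline"))
  utils::write.csv(as.data.frame(timeline)[, c("phase", "start_s", "end_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-second true labels implied by a timeline
#'
#' Expands interval annotations to one label per second: second `t` carries
#' label `L` iff some row has `start_s <= t <= end_s`; uncovered seconds are
#' `OTHER`.
#'
#' @param timeline a [phase_timeline()].
#' @param duration_s total length in seconds; defaults to `max(end_s) + 1`.
#' @return Character vector of length `duration_s`, element `t + 1` being the
#'   label of second `t`.
#' @export
labels_from_timeline <- function(timeline, duration_s = NULL) {
  stopifnot(inherits(timeline, "phase_timeline"))
  if (is.null(duration_s)) duration_s <- max(timeline$end_s) + 1L
  lab <- rep("OTHER", duration_s)
  for (r in seq_len(nrow(timeline))) {
    lo <- max(0L, timeline$start_s[r])
    hi <- min(duration_s - 1L, timeline$end_s[r])
    if (lo <= hi) lab[(lo:hi) + 1L] <- timeline$phase[r]
  }
  lab
}

timeline_duration <- function(timeline) max(timeline$end_s) + 1L

#' @export
print.phase_timeline <- function(x, ...) {
  cat("Phase timeline for", attr(x, "source_id") %||% "<unnamed>",
      sprintf("(%d s)\n", timeline_duration(x)))
  print(as.data.frame(x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
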