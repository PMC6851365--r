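#' Read and write score / decision streams and segmentation results
#'
#' The pipeline's on-disk interchange formats are plain CSV and JSON so any
#' stage can be rerun in isolation: score streams as
#' `time_s,score_ccc,score_nuclear,score_other`; decision streams as
#' `time_s,ave_ccc,ave_nuclear,ave_other,decided_phase`; segmentation
#' results as JSON with missing boundaries serialized as `null`.
#'
#' @param scores,decisions,result object to write.
#' @param path file path.
#' @return Readers return the object; writers return `path` invisibly.
#' @name stream_io
NULL

#' @rdname stream_io
#' @export
write_scores <- function(scores, path) {
  validate_score_stream(scores)
  utils::write.csv(scores[, c("time_s", score_cols())], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_scores <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_score_stream(s)
  attr(s, "source_id") <- sub("\\.[^.]*$", "", basename(path))
  s
}

#' @rdname stream_io
#' @export
write_decisions <- function(decisions, path) {
  utils::write.csv(decisions[, c("time_s", ave_cols(), "decided_phase")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_decisions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", ave_cols(), "decided_phase")
  if (!all(need %in% names(d)))
    stop("decision CSV needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  attr(d, "source_id") <- sub("\\.[^.]*$", "", basename(path))
  class(d) <- c("decision_stream", "data.frame")
  d
}

#' @rdname stream_io
#' @export
write_segmentation <- function(result, path) {
  stopifnot(inherits(result, "segmentation_result"))
  obj <- list(
    ccc = list(start_s = na_null(result$ccc_start_s),
               end_s = na_null(result$ccc_end_s)),
    nuclear = list(start_s = na_null(result$nuclear_start_s),
                   end_s = na_null(result$nuclear_end_s)),
    end_rule = result$end_rule,
    window_len = result$window_len)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_segmentation <- function(path) {
  obj <- jsonlite::read_json(path)
  res <- list(ccc_start_s = null_na(obj$ccc$start_s),
              ccc_end_s = null_na(obj$ccc$end_s),
              nuclear_start_s = null_na(obj$nuclear$start_s),
              nuclear_end_s = null_na(obj$nuclear$end_s),
              end_rule = obj$end_rule, window_len = obj$window_len,
              source_id = sub("\\.[^.]*$", "", basename(path)),
              decisions = NULL)
  class(res) <- "segmentation_result"
  res
}

na_null <- function(x) if (is.null(x) || is.na(x)) NULL else as.integer(x)
null_na <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)

#' Write a simulated cohort to a directory
#'
#' Lays out one sub-directory per surgery with `truth.csv` and `scores.csv`,
#' plus a top-level `manifest.json` recording the per-surgery seeds, so a
#' cohort is fully reproducible and consumable file-by-file.
#'
#' @param cohort output of [make_test_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$truths)) {
    sd <- file.path(dir, id)
    dir.create(sd, showWarnings = FALSE)
    write_annotation(cohort$truths[[id]], file.path(sd, "truth.csv"))
    write_scores(cohort$scores[[id]], file.path(sd, "scores.csv"))
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return List with `truths` and `scores`, named by surgery id.
#' @export
read_cohort <- function(dir) {
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  truths <- lapply(ids, function(id)
    load_annotation(file.path(dir, id, "truth.csv"), source_id = id))
  scores <- lapply(ids, function(id) {
    s <- read_scores(file.path(dir, id, "scores.csv"))
    attr(s, "source_id") <- id
    s
  })
  names(truths) <- ids; names(scores) <- ids
  list(truths = truths, scores = scores)
}
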