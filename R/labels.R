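#' Phase labels of the three-class recognition task
#'
#' The recognizer distinguishes the two phases that matter most for surgical
#' skill assessment in phacoemulsification cataract surgery — continuous
#' curvilinear capsulorrhexis (`"CCC"`) and nuclear extraction (`"NUCLEAR"`)
#' — and lumps every remaining maneuver (incisions, viscoelastic injection,
#' cortical aspiration, IOL insertion, ...) into `"OTHER"`.
#'
#' The class index order `(CCC, NUCLEAR, OTHER)` is fixed throughout the
#' package: score triples, confusion matrices and tie-breaking all use it.
#'
#' @return Character vector `c("CCC", "NUCLEAR", "OTHER")`.
#' @export
#' @examples
#' phase_labels()
phase_labels <- function() c("CCC", "NUCLEAR", "OTHER")

# validate/normalize a vector of phase labels to the canonical set
as_phase_label <- function(x) {
  x <- toupper(as.character(x))
  x[x %in% c("OTHERS", "OTHER")] <- "OTHER"
  x[x %in% c("NUCLEAR EXTRACTION", "NUCLEAR_EXTRACTION", "NUCLEAR")] <- "NUCLEAR"
  bad <- setdiff(unique(x), phase_labels())
  if (length(bad) > 0L)
    stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x
}

# column names used for score / average triples in CSV interfaces
score_cols <- function() c("score_ccc", "score_nuclear", "score_other")
ave_cols <- function() c("ave_ccc", "ave_nuclear", "ave_other")
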