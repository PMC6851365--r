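#' Specification of a synthetic cataract surgery
#'
#' Describes the statistical structure of a simulated surgery timeline. The
#' fixed segment order is OTHER, CCC, OTHER, NUCLEAR, OTHER: a surgery opens
#' with incision/viscoelastic work, then the capsulorrhexis, then hydro
#' maneuvers, then nuclear extraction, then cortical aspiration and IOL
#' insertion. Segment durations are drawn independently from normal
#' distributions truncated below at `min_duration_s`.
#'
#' Defaults emulate the clinical distribution this package models: CCC mean
#' 42 s (SD 44), nuclear extraction 133 s (SD 85), and 359 s (SD 163) of
#' total OTHER time split over the three OTHER segments in proportions
#' (0.33, 0.17, 0.50), with the OTHER SD split so the segment variances sum
#' to the total variance. Total expected duration is about 534 s. Because
#' the SDs are comparable to the means, truncation shifts realized means
#' upward; see the methods vignette.
#'
#' @param duration_means_s,duration_sds_s numeric length-5 per-segment means
#'   and SDs, in seconds, in segment order.
#' @param min_duration_s lower truncation point, seconds (default 5, the
#'   default smoothing window, so every phase is detectable).
#' @param other_split proportions of the total OTHER mean assigned to the
#'   pre-CCC, mid, and post-NUCLEAR segments; used only to build defaults.
#' @return A `surgery_spec` list.
#' @export
surgery_spec <- function(duration_means_s = NULL, duration_sds_s = NULL,
                         min_duration_s = 5,
                         other_split = c(0.33, 0.17, 0.50)) {
  stopifnot(length(other_split) == 3L, all(other_split > 0))
  other_split <- other_split / sum(other_split)
  if (is.null(duration_means_s))
    duration_means_s <- c(359 * other_split[1], 42, 359 * other_split[2],
                          133, 359 * other_split[3])
  if (is.null(duration_sds_s))
    duration_sds_s <- c(163 * sqrt(other_split[1]), 44,
                        163 * sqrt(other_split[2]), 85,
                        163 * sqrt(other_split[3]))
  stopifnot(length(duration_means_s) == 5L, length(duration_sds_s) == 5L)
  if (any(duration_means_s <= 0) || any(duration_sds_s < 0))
    stop("duration means must be positive and SDs non-negative", call. = FALSE)
  if (min_duration_s <= 0) stop("min_duration_s must be positive", call. = FALSE)
  structure(list(segment_order = c("OTHER", "CCC", "OTHER", "NUCLEAR", "OTHER"),
                 duration_means_s = duration_means_s,
                 duration_sds_s = duration_sds_s,
                 min_duration_s = min_duration_s),
            class = "surgery_spec")
}

# normal truncated below at a, by inverse-CDF (exact, no rejection)
rtnorm_lower <- function(n, mean, sd, a) {
  if (sd == 0) return(rep(max(mean, a), n))
  plo <- stats::pnorm(a, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate a ground-truth surgery timeline
#'
#' Draws the five segment durations of [surgery_spec()] (truncated-normal,
#' rounded to whole seconds, at least `min_duration_s`) and lays the
#' segments contiguously from second 0.
#'
#' @param spec a [surgery_spec()].
#' @param seed integer seed; the draw is reproducible under it. `NULL` uses
#'   (and advances) the caller's RNG stream.
#' @param source_id surgery identifier.
#' @return A [phase_timeline()] with one row per segment (OTHER rows
#'   included, so the total duration is recoverable).
#' @export
#' @examples
#' simulate_timeline(surgery_spec(), seed = 1)
simulate_timeline <- function(spec = surgery_spec(), seed = NULL,
                              source_id = "sim") {
  stopifnot(inherits(spec, "surgery_spec"))
  with_local_seed(seed, {
    d <- vapply(seq_along(spec$segment_order), function(i) {
      x <- rtnorm_lower(1L, spec$duration_means_s[i], spec$duration_sds_s[i],
                        spec$min_duration_s)
      max(as.integer(round(x)), as.integer(ceiling(spec$min_duration_s)))
    }, integer(1))
    ends <- cumsum(d) - 1L
    starts <- c(0L, head(ends, -1L) + 1L)
    phase_timeline(spec$segment_order, starts, ends, source_id = source_id)
  })
}

#' Per-frame confusion model for score simulation
#'
#' A stochastic stand-in for the trained frame classifier: row `r` of the
#' 3x3 row-stochastic `matrix` gives the probability that a frame whose true
#' class is `r` is scored as each class (class order CCC, NUCLEAR, OTHER).
#' The default rows are the per-frame confusion rates this pipeline is built
#' around — per-class accuracies 90.7% (CCC), 94.5% (nuclear extraction) and
#' 97.9% (others), with CCC/nuclear cross-confusion essentially zero.
#'
#' @param matrix 3x3 row-stochastic matrix.
#' @param concentration score sharpness, >= 1; the emitted class's score is
#'   at least `concentration / (concentration + 1)`, so the per-frame argmax
#'   always equals the emitted class.
#' @param sticky probability in `[0, 1)` that a misclassified frame's
#'   emitted class is copied by the following frame, producing error runs of
#'   geometric length near phase transitions (0 = independent errors, the
#'   default).
#' @return A `confusion_model`.
#' @export
confusion_model <- function(matrix = default_confusion_matrix(),
                            concentration = 8, sticky = 0) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(3L, 3L)))
    stop("confusion matrix must be 3x3", call. = FALSE)
  if (any(matrix < 0) || any(matrix > 1))
    stop("confusion matrix entries must lie in [0,1]", call. = FALSE)
  if (any(abs(rowSums(matrix) - 1) > 1e-8))
    stop("confusion matrix rows must sum to 1", call. = FALSE)
  if (concentration < 1) stop("concentration must be >= 1", call. = FALSE)
  if (sticky < 0 || sticky >= 1) stop("sticky must be in [0,1)", call. = FALSE)
  dimnames(matrix) <- list(truth = phase_labels(), scored = phase_labels())
  structure(list(matrix = matrix, concentration = concentration,
                 sticky = sticky),
            class = "confusion_model")
}

#' @rdname confusion_model
#' @export
default_confusion_matrix <- function() {
  rbind(c(0.907, 0.000, 0.093),
        c(0.000, 0.945, 0.055),
        c(0.009, 0.012, 0.979))
}

#' @rdname confusion_model
#' @export
identity_confusion <- function(concentration = 8)
  confusion_model(diag(3), concentration = concentration)

#' Simulate a per-frame classifier score stream
#'
#' For each second of the surgery, the emitted class is drawn from the
#' confusion-matrix row of the true class; the score triple is then a sharp
#' probability vector peaked on the emitted class:
#' `(c * onehot + u) / (c + 1)` with `u ~ Dirichlet(1,1,1)` and
#' `c = concentration`. Because `c >= 1`, the argmax of every triple equals
#' the emitted class, so per-frame decision rates reproduce the confusion
#' rows in expectation.
#'
#' @param truth a [phase_timeline()].
#' @param duration_s stream length in seconds; defaults to the timeline's.
#' @param model a [confusion_model()].
#' @param seed integer seed (reproducible) or `NULL`.
#' @return A score stream `data.frame` (`time_s`, `score_ccc`,
#'   `score_nuclear`, `score_other`) with the surgery's `source_id` attached.
#' @export
simulate_scores <- function(truth, duration_s = NULL,
                            model = confusion_model(), seed = NULL) {
  stopifnot(inherits(model, "confusion_model"))
  labels <- labels_from_timeline(truth, duration_s)
  n <- length(labels)
  idx <- match(labels, phase_labels())
  with_local_seed(seed, {
    emitted <- integer(n)
    prev_err <- NA_integer_
    for (i in seq_len(n)) {
      if (!is.na(prev_err) && model$sticky > 0 &&
          stats::runif(1) < model$sticky) {
        emitted[i] <- prev_err
      } else {
        emitted[i] <- sample.int(3L, 1L, prob = model$matrix[idx[i], ])
      }
      prev_err <- if (emitted[i] != idx[i]) emitted[i] else NA_integer_
    }
    u <- matrix(stats::rgamma(3L * n, shape = 1), n, 3L)
    u <- u / rowSums(u)
    cc <- model$concentration
    sc <- u
    sc[cbind(seq_len(n), emitted)] <- sc[cbind(seq_len(n), emitted)] + cc
    sc <- sc / (cc + 1)
    s <- data.frame(time_s = seq_len(n) - 1L, score_ccc = sc[, 1],
                    score_nuclear = sc[, 2], score_other = sc[, 3])
    attr(s, "source_id") <- attr(truth, "source_id")
    s
  })
}

#' Render labeled toy frames for a timeline
#'
#' A desk-scale stand-in for surgical video: each phase has a distinct
#' dominant hue (CCC reddish, NUCLEAR bluish, OTHER greenish — matching the
#' conventional timeline coloring for this task) overlaid with random
#' rectangular "instrument" textures, per-frame pixel noise and brightness
#' jitter, so frame classification is learnable from color statistics but
#' not pixel-trivial.
#'
#' @param timeline a [phase_timeline()].
#' @param resolution `(width, height)` in pixels.
#' @param seed integer seed or `NULL`.
#' @param noise_sd per-pixel Gaussian noise SD (on the `[0,1]` scale).
#' @param brightness_sd per-frame global brightness jitter SD.
#' @param n_shapes number of random texture rectangles per frame.
#' @return A `frame_stream`: list of frame records, each a list with
#'   `time_s`, `image` (H x W x 3 array in `[0,1]`), `source_id`, `label`.
#' @export
render_toy_frames <- function(timeline, resolution = c(32L, 32L), seed = NULL,
                              noise_sd = 0.04, brightness_sd = 0.04,
                              n_shapes = 3L) {
  stopifnot(length(resolution) == 2L, all(resolution >= 4L))
  w <- as.integer(resolution[1]); h <- as.integer(resolution[2])
  labels <- labels_from_timeline(timeline)
  base <- rbind(CCC = c(0.70, 0.20, 0.20),
                NUCLEAR = c(0.20, 0.25, 0.70),
                OTHER = c(0.20, 0.65, 0.25))
  sid <- attr(timeline, "source_id") %||% "toy"
  with_local_seed(seed, {
    frames <- vector("list", length(labels))
    for (t in seq_along(labels)) {
      img <- array(0, dim = c(h, w, 3L))
      mu <- base[labels[t], ] + stats::rnorm(1L, 0, brightness_sd)
      for (ch in 1:3)
        img[, , ch] <- mu[ch] + stats::rnorm(h * w, 0, noise_sd)
      for (k in seq_len(n_shapes)) {
        rh <- sample.int(max(2L, h %/% 3L), 1L) + 1L
        rw <- sample.int(max(2L, w %/% 3L), 1L) + 1L
        r0 <- sample.int(h - rh + 1L, 1L)
        c0 <- sample.int(w - rw + 1L, 1L)
        shift <- stats::runif(3L, -0.25, 0.25)
        for (ch in 1:3)
          img[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L), ch] <-
            img[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L), ch] + shift[ch]
      }
      img[img < 0] <- 0; img[img > 1] <- 1
      frames[[t]] <- list(time_s = t - 1L, image = img, source_id = sid,
                          label = labels[t])
    }
    structure(frames, class = "frame_stream", source_id = sid)
  })
}

#' Generate a paired cohort of truths and score streams
#'
#' Emulates a held-out test set of surgeries: `n_surgeries` independent
#' timelines drawn from `spec`, each with a simulated score stream under
#' `confusion`. Fully deterministic under `seed` (per-surgery sub-seeds are
#' drawn once from the master seed).
#'
#' @param n_surgeries number of surgeries (>= 1).
#' @param spec a [surgery_spec()].
#' @param confusion a [confusion_model()].
#' @param seed master integer seed.
#' @return List with `truths` (list of [phase_timeline()]) and `scores`
#'   (list of score streams), both named by surgery id, plus a `manifest`
#'   data.frame of per-surgery seeds.
#' @export
make_test_cohort <- function(n_surgeries, spec = surgery_spec(),
                             confusion = confusion_model(), seed = NULL) {
  stopifnot(n_surgeries >= 1L)
  sub <- with_local_seed(seed,
    matrix(sample.int(.Machine$integer.max, 2L * n_surgeries), ncol = 2L))
  ids <- sprintf("surgery%03d", seq_len(n_surgeries))
  truths <- vector("list", n_surgeries); names(truths) <- ids
  scores <- vector("list", n_surgeries); names(scores) <- ids
  for (i in seq_len(n_surgeries)) {
    truths[[i]] <- simulate_timeline(spec, seed = sub[i, 1], source_id = ids[i])
    scores[[i]] <- simulate_scores(truths[[i]], model = confusion,
                                   seed = sub[i, 2])
  }
  list(truths = truths, scores = scores,
       manifest = data.frame(source_id = ids, timeline_seed = sub[, 1],
                             score_seed = sub[, 2]))
}
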