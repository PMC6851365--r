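#' Build the Inception-style phase recognition network
#'
#' Constructs the convolutional classifier used for per-frame phase
#' recognition: a convolutional stem (3x3 convs and max-pools), three stages
#' of Inception modules (factorized 5x5 / 7x7 / expanded 3x3 branches with
#' filter concatenation) separated by grid-reduction modules, global average
#' pooling, two fully connected layers, and a 3-way softmax head. All convs
#' carry batch normalization and ReLU. At the default width and module
#' counts the layer schedule is, for a 168x299x3 input: stem to a 35x18x288
#' grid, reduction to 17x8x768, reduction to 8x3x1280, modules to 8x3x2048,
#' then global pooling and fully connected layers of 2048 and 1024 units.
#'
#' `width_mult` scales every channel count (minimum 4) and `fc_sizes` /
#' `inception_counts` shrink the head and the number of modules per stage,
#' so the same schedule is trainable at toy scale on a CPU. The smallest
#' admissible input grid is 75x75; smaller inputs make a pooling stage
#' collapse and raise a construction error.
#'
#' @param input_shape integer `(H, W, 3)`.
#' @param n_classes number of output classes (default 3).
#' @param width_mult channel width multiplier in (0, 1].
#' @param inception_counts modules per stage, default `c(3, 4, 2)`.
#' @param fc_sizes sizes of the two fully connected layers,
#'   default `c(2048, 1024)` (scaled by `width_mult`).
#' @param seed integer seed for weight initialization, or `NULL`.
#' @return A `cnn_classifier` object.
#' @export
#' @examples
#' \donttest{
#' net <- build_network(c(75, 75, 3), width_mult = 1 / 16, seed = 1)
#' }
build_network <- function(input_shape, n_classes = 3L, width_mult = 1,
                          inception_counts = c(3L, 4L, 2L),
                          fc_sizes = c(2048L, 1024L), seed = NULL) {
  stopifnot(length(input_shape) == 3L, input_shape[3] == 3L,
            width_mult > 0, width_mult <= 1, length(inception_counts) == 3L)
  ch <- function(c) max(4L, as.integer(round(c * width_mult)))

  conv <- conv_spec
  a_module <- function(pool_ch) inception_spec(list(
    list(conv(1, 1, ch(64))),
    list(conv(1, 1, ch(48)), conv(5, 5, ch(64), pad = "same")),
    list(conv(1, 1, ch(64)), conv(3, 3, ch(96), pad = "same"),
         conv(3, 3, ch(96), pad = "same")),
    list(avgpool_spec(), conv(1, 1, ch(pool_ch)))))
  reduction_a <- inception_spec(list(
    list(conv(3, 3, ch(384), stride = 2)),
    list(conv(1, 1, ch(64)), conv(3, 3, ch(96), pad = "same"),
         conv(3, 3, ch(96), stride = 2)),
    list(maxpool_spec())))
  b_module <- function(c7) inception_spec(list(
    list(conv(1, 1, ch(192))),
    list(conv(1, 1, ch(c7)), conv(1, 7, ch(c7), pad = "same"),
         conv(7, 1, ch(192), pad = "same")),
    list(conv(1, 1, ch(c7)), conv(7, 1, ch(c7), pad = "same"),
         conv(1, 7, ch(c7), pad = "same"), conv(7, 1, ch(c7), pad = "same"),
         conv(1, 7, ch(192), pad = "same")),
    list(avgpool_spec(), conv(1, 1, ch(192)))))
  reduction_b <- inception_spec(list(
    list(conv(1, 1, ch(192)), conv(3, 3, ch(320), stride = 2)),
    list(conv(1, 1, ch(192)), conv(1, 7, ch(192), pad = "same"),
         conv(7, 1, ch(192), pad = "same"), conv(3, 3, ch(192), stride = 2)),
    list(maxpool_spec())))
  split33 <- function(c_out) inception_spec(list(
    list(conv(1, 3, ch(c_out), pad = "same")),
    list(conv(3, 1, ch(c_out), pad = "same"))))
  e_module <- function() inception_spec(list(
    list(conv(1, 1, ch(320))),
    list(conv(1, 1, ch(384)), split33(384)),
    list(conv(1, 1, ch(448)), conv(3, 3, ch(384), pad = "same"),
         split33(384)),
    list(avgpool_spec(), conv(1, 1, ch(192)))))

  specs <- c(
    list(conv(3, 3, ch(32), stride = 2),
         conv(3, 3, ch(32)),
         conv(3, 3, ch(64), pad = "same"),
         maxpool_spec(),
         conv(1, 1, ch(80)),
         conv(3, 3, ch(192)),
         maxpool_spec()),
    lapply(seq_len(inception_counts[1]), function(i)
      a_module(if (i == 1L) 32 else 64)),
    list(reduction_a),
    lapply(seq_len(inception_counts[2]), function(i)
      b_module(c(128, 160, 160, 192)[min(i, 4L)])),
    list(reduction_b),
    lapply(seq_len(inception_counts[3]), function(i) e_module()),
    list(gap_spec(),
         dense_spec(max(8L, as.integer(round(fc_sizes[1] * width_mult)))),
         dense_spec(max(8L, as.integer(round(fc_sizes[2] * width_mult)))),
         dense_spec(n_classes, act = "linear")))

  built <- with_local_seed(seed, init_layers(specs, as.integer(input_shape)))
  structure(list(layers = built$layers, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), width_mult = width_mult,
                 loss_log = numeric(0)),
            class = c("cnn_classifier", "phase_classifier"))
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cat("Inception-style phase classifier\n")
  cat("  input:", paste(x$input_shape, collapse = "x"),
      " classes:", x$n_classes, " width:", x$width_mult, "\n")
  cat("  parameters:", format(n_parameters(x$layers), big.mark = ","), "\n")
  if (length(x$loss_log) > 0L)
    cat("  trained", length(x$loss_log), "epochs; final loss",
        signif(tail(x$loss_log, 1), 4), "\n")
  invisible(x)
}

n_parameters <- function(layers) {
  n <- 0
  for (l in layers) {
    if (l$type == "conv") {
      n <- n + length(l$w) + length(l$b)
      if (isTRUE(l$bn)) n <- n + 2L * length(l$gamma)
    } else if (l$type == "dense") {
      n <- n + length(l$w) + length(l$b)
    } else if (l$type == "inception") {
      for (b in l$branches) n <- n + n_parameters(b)
    }
  }
  n
}

#' Training configuration
#'
#' Defaults are the reference operating point for fine-tuning this
#' recognizer: batch size 32, momentum SGD with learning rate 1e-4 and
#' momentum 0.9, multi-class log loss, at most 300 epochs, minority-class
#' oversampling, and the full augmentation pipeline. For training small
#' randomly initialized networks a larger learning rate (e.g. 0.01) is
#' appropriate; see the methods vignette.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param max_epochs maximum training epochs.
#' @param seed integer seed controlling sample order, augmentation draws and
#'   (via [build_network()]) initialization; same seed, same loss log.
#' @param augmentation an [augmentation_config()].
#' @param balance_classes when `TRUE`, every minority class is resampled
#'   with replacement within each epoch so per-class counts match the
#'   majority class.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement) when a validation set is supplied.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 32L, learning_rate = 1e-4,
                            momentum = 0.9, max_epochs = 300L, seed = NULL,
                            augmentation = augmentation_config(),
                            balance_classes = TRUE, patience = 20L) {
  stopifnot(batch_size >= 1L, learning_rate > 0, momentum >= 0, momentum < 1,
            max_epochs >= 1L, inherits(augmentation, "augmentation_config"))
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), seed = seed,
                 augmentation = augmentation,
                 balance_classes = isTRUE(balance_classes),
                 patience = as.integer(patience)),
            class = "training_config")
}

#' Train the phase classifier on labeled frames
#'
#' Optimizes the multi-class log loss by momentum SGD. When
#' `balance_classes` is set, each epoch resamples every minority class with
#' replacement up to the majority count, so the imbalanced phase
#' distribution (OTHER frames dominate a surgery) does not bias the
#' classifier. Augmentation is applied on the fly to each presented frame.
#' With a validation set, training stops early once validation loss has not
#' improved for `patience` epochs, and the best-validation weights are kept.
#'
#' @param classifier a `cnn_classifier` from [build_network()].
#' @param frames a `frame_stream` whose records carry `label`s (e.g. from
#'   [render_toy_frames()]), or any list of `list(image=, label=)` records.
#' @param config a [training_config()].
#' @param validation optional labeled frame list for early stopping.
#' @param verbose print per-epoch losses.
#' @return The trained classifier; `$loss_log` holds per-epoch mean training
#'   loss (and `$val_loss_log` validation loss, when supplied).
#' @export
train_classifier <- function(classifier, frames, config = training_config(),
                             validation = NULL, verbose = FALSE) {
  stopifnot(inherits(classifier, "cnn_classifier"),
            inherits(config, "training_config"))
  labels <- vapply(frames, function(f) f$label, character(1))
  labels <- as_phase_label(labels)
  present <- phase_labels() %in% labels
  if (!all(present))
    stop("training error: no frames for class(es) ",
         paste(phase_labels()[!present], collapse = ", "), call. = FALSE)
  y <- match(labels, phase_labels())

  with_local_seed(config$seed, {
    best <- NULL; best_val <- Inf; bad <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      idx <- if (config$balance_classes) balanced_indices(y) else
        sample(seq_along(y))
      losses <- numeric(0)
      for (b0 in seq(1L, length(idx), by = config$batch_size)) {
        bi <- idx[b0:min(b0 + config$batch_size - 1L, length(idx))]
        xb <- assemble_batch(frames, bi, config$augmentation)
        step <- sgd_step(classifier$layers, xb, y[bi],
                         config$learning_rate, config$momentum)
        classifier$layers <- step$layers
        losses <- c(losses, step$loss)
      }
      epoch_loss <- mean(losses)
      if (!is.finite(epoch_loss))
        stop("divergence error: NaN loss at epoch ", epoch,
             " (batch_size=", config$batch_size,
             ", learning_rate=", config$learning_rate,
             ", momentum=", config$momentum, ")", call. = FALSE)
      classifier$loss_log <- c(classifier$loss_log, epoch_loss)
      if (!is.null(validation)) {
        vl <- eval_log_loss(classifier, validation)
        classifier$val_loss_log <- c(classifier$val_loss_log, vl)
        if (vl < best_val - 1e-8) {
          best_val <- vl; best <- classifier$layers; bad <- 0L
        } else bad <- bad + 1L
        if (verbose) message(sprintf("epoch %d: loss %.4f val %.4f",
                                     epoch, epoch_loss, vl))
        if (bad >= config$patience) break
      } else if (verbose) {
        message(sprintf("epoch %d: loss %.4f", epoch, epoch_loss))
      }
    }
    if (!is.null(best)) classifier$layers <- best
    classifier
  })
}

# within-epoch oversampling: minority classes resampled with replacement to
# the majority count, then the whole epoch shuffled
balanced_indices <- function(y) {
  tab <- table(y)
  n_max <- max(tab)
  idx <- unlist(lapply(as.integer(names(tab)), function(cl) {
    i <- which(y == cl)
    if (length(i) < n_max) c(i, sample(i, n_max - length(i), replace = TRUE))
    else i
  }))
  sample(idx)
}

assemble_batch <- function(frames, bi, augmentation = NULL) {
  d <- dim(frames[[bi[1]]]$image)
  xb <- array(0, dim = c(d, length(bi)))
  for (k in seq_along(bi)) {
    img <- frames[[bi[k]]]$image
    if (!is.null(augmentation)) img <- augment_frame(img, augmentation)
    xb[, , , k] <- img
  }
  xb
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

sgd_step <- function(layers, xb, yb, lr, momentum) {
  fwd <- net_forward(layers, xb, training = TRUE)
  p <- softmax_cols(fwd$out)
  n <- length(yb)
  loss <- -mean(log(pmax(p[cbind(yb, seq_len(n))], 1e-12)))
  dz <- p
  dz[cbind(yb, seq_len(n))] <- dz[cbind(yb, seq_len(n))] - 1
  dz <- dz / n
  bwd <- net_backward(fwd$layers, fwd$caches, dz)
  list(layers = net_update(bwd$layers, lr, momentum), loss = loss)
}

eval_log_loss <- function(classifier, frames, batch_size = 32L) {
  y <- match(as_phase_label(vapply(frames, `[[`, character(1), "label")),
             phase_labels())
  tot <- 0
  for (b0 in seq(1L, length(frames), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, length(frames))
    xb <- assemble_batch(frames, bi)
    p <- softmax_cols(net_forward(classifier$layers, xb)$out)
    tot <- tot + sum(-log(pmax(p[cbind(y[bi], seq_along(bi))], 1e-12)))
  }
  tot / length(frames)
}

#' Per-frame class scores for a batch of frames
#'
#' Deterministic inference pass (batch-norm in inference mode, no
#' augmentation): softmax class probabilities for each frame.
#'
#' @param classifier a `cnn_classifier`.
#' @param frames a `frame_stream` or list of frame records.
#' @param batch_size inference batch size.
#' @return `n x 3` matrix of class probabilities (columns CCC, NUCLEAR,
#'   OTHER), rows summing to 1.
#' @export
predict_scores <- function(classifier, frames, batch_size = 32L) {
  out <- matrix(0, length(frames), 3L,
                dimnames = list(NULL, phase_labels()))
  for (b0 in seq(1L, length(frames), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, length(frames))
    xb <- assemble_batch(frames, bi)
    out[bi, ] <- t(softmax_cols(net_forward(classifier$layers, xb)$out))
  }
  out
}

#' Classify a time-ordered frame stream
#'
#' A pure per-frame map: one score triple per frame, carrying the frame's
#' `time_s`; no temporal state is involved (smoothing is a separate stage,
#' [smooth_stream()]).
#'
#' @param classifier a `cnn_classifier` or `confusion_classifier`.
#' @param frames a `frame_stream`, time-ordered at contiguous seconds.
#' @param ... passed to methods (`seed` for the confusion classifier).
#' @return A score stream `data.frame`.
#' @export
classify_stream <- function(classifier, frames, ...)
  UseMethod("classify_stream")

check_frame_order <- function(frames) {
  t <- vapply(frames, function(f) as.integer(f$time_s), integer(1))
  if (length(t) > 1L && any(diff(t) <= 0L))
    stop("ordering error: frames must be strictly time-ordered", call. = FALSE)
  t
}

#' @export
classify_stream.cnn_classifier <- function(classifier, frames, ...) {
  t <- check_frame_order(frames)
  if (length(frames) == 0L)
    return(data.frame(time_s = integer(0), score_ccc = numeric(0),
                      score_nuclear = numeric(0), score_other = numeric(0)))
  p <- predict_scores(classifier, frames, ...)
  s <- data.frame(time_s = t, score_ccc = p[, 1], score_nuclear = p[, 2],
                  score_other = p[, 3])
  attr(s, "source_id") <- attr(frames, "source_id")
  s
}

#' Confusion-model test classifier
#'
#' A stochastic stand-in classifier for exercising the temporal stages
#' without a trained network: frames must carry true labels, and scores are
#' drawn from the confusion model exactly as in [simulate_scores()].
#'
#' @param model a [confusion_model()].
#' @return A `confusion_classifier`.
#' @export
confusion_classifier <- function(model = confusion_model()) {
  stopifnot(inherits(model, "confusion_model"))
  structure(list(model = model),
            class = c("confusion_classifier", "phase_classifier"))
}

#' @rdname confusion_classifier
#' @param classifier,frames,... see [classify_stream()]; `seed` makes the
#'   draw reproducible.
#' @param seed integer seed or `NULL`.
#' @export
classify_stream.confusion_classifier <- function(classifier, frames,
                                                 seed = NULL, ...) {
  t <- check_frame_order(frames)
  if (length(frames) == 0L)
    return(data.frame(time_s = integer(0), score_ccc = numeric(0),
                      score_nuclear = numeric(0), score_other = numeric(0)))
  labels <- as_phase_label(vapply(frames, `[[`, character(1), "label"))
  dur <- max(t) + 1L
  # build a per-second timeline-equivalent truth for the simulator
  idx <- match(labels, phase_labels())
  m <- classifier$model
  with_local_seed(seed, {
    n <- length(t)
    emitted <- vapply(idx, function(r)
      sample.int(3L, 1L, prob = m$matrix[r, ]), integer(1))
    u <- matrix(stats::rgamma(3L * n, shape = 1), n, 3L)
    u <- u / rowSums(u)
    sc <- u
    sc[cbind(seq_len(n), emitted)] <- sc[cbind(seq_len(n), emitted)] +
      m$concentration
    sc <- sc / (m$concentration + 1)
    s <- data.frame(time_s = t, score_ccc = sc[, 1], score_nuclear = sc[, 2],
                    score_other = sc[, 3])
    attr(s, "source_id") <- attr(frames, "source_id")
    s
  })
}
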