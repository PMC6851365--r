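test_that("simulated score triples are probability vectors peaked on the emitted class", {
  tl <- fixture_timeline()
  s <- simulate_scores(tl, model = confusion_model(), seed = 4)
  m <- as.matrix(s[, c("score_ccc", "score_nuclear", "score_other")])
  expect_true(all(abs(rowSums(m) - 1) < 1e-6))
  expect_true(all(m >= 0))
  expect_true(all(apply(m, 1, max) >= 8 / 9))   # concentration 8 floor
})

test_that("identity confusion reproduces the truth frame by frame", {
  tl <- fixture_timeline()
  s <- simulate_scores(tl, model = identity_confusion(), seed = 1)
  m <- as.matrix(s[, c("score_ccc", "score_nuclear", "score_other")])
  decided <- phase_labels()[max.col(m)]
  expect_equal(decided, labels_from_timeline(tl))
})

test_that("simulated streams are reproducible under a seed", {
  tl <- fixture_timeline()
  expect_identical(simulate_scores(tl, model = confusion_model(), seed = 42),
                   simulate_scores(tl, model = confusion_model(), seed = 42))
  s2 <- simulate_scores(tl, model = confusion_model(), seed = 43)
  expect_false(identical(
    simulate_scores(tl, model = confusion_model(), seed = 42), s2))
})

test_that("long-run emission frequencies converge to the confusion rows", {
  n <- 100000L
  tl <- phase_timeline("OTHER", 0, n - 1)      # degenerate: all OTHER
  s <- simulate_scores(tl, model = confusion_model(), seed = 8)
  m <- as.matrix(s[, c("score_ccc", "score_nuclear", "score_other")])
  frac <- tabulate(max.col(m), 3) / n
  target <- default_confusion_matrix()[3, ]    # OTHER row
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(frac - target) <= 3 * se + 1e-12))
})

test_that("confusion model validation rejects non-stochastic matrices", {
  bad <- diag(3); bad[1, 1] <- 0.5
  expect_error(confusion_model(bad), "sum to 1")
  bad2 <- matrix(c(1.2, -0.2, 0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_error(confusion_model(bad2), "\\[0,1\\]")
})

test_that("the network follows the stem/inception/pool grid schedule", {
  # full module counts at reduced width; grid sizes must match the
  # reference schedule for a 168x299 input
  net <- build_network(c(168, 299, 3), width_mult = 1 / 8, seed = 1)
  shapes <- lapply(net$layers, `[[`, "out_shape")
  grid <- function(i) shapes[[i]][1:2]
  expect_equal(grid(1), c(83L, 149L))   # stem conv /2
  expect_equal(grid(2), c(81L, 147L))
  expect_equal(grid(4), c(40L, 73L))    # max pool
  expect_equal(grid(7), c(18L, 35L))    # inception stage A input grid
  expect_equal(grid(11), c(8L, 17L))    # after grid reduction
  expect_equal(grid(16), c(3L, 8L))     # after second reduction
  final <- shapes[[length(shapes)]]
  expect_equal(final, 3L)               # softmax head size
})

test_that("forward pass yields a deterministic probability triple per frame", {
  net <- build_network(c(75, 75, 3), width_mult = 1 / 16,
                       inception_counts = c(1, 1, 1), seed = 2)
  img <- array(runif(75 * 75 * 3), c(75, 75, 3))
  fr <- list(list(time_s = 0L, image = img, source_id = "x"))
  p1 <- predict_scores(net, fr)
  p2 <- predict_scores(net, fr)
  expect_equal(dim(p1), c(1L, 3L))
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  expect_true(all(p1 >= 0))
  expect_identical(p1, p2)              # inference is deterministic
})

test_that("inputs below the minimum grid raise a construction error", {
  expect_error(build_network(c(32, 32, 3), width_mult = 1 / 16),
               "construction error")
})

test_that("classify_stream is a pure length-preserving map", {
  frames <- lapply(0:9, function(t)
    list(time_s = t, image = array(0.5, c(8, 8, 3)), source_id = "s",
         label = "OTHER"))
  cls <- confusion_classifier(identity_confusion())
  s <- classify_stream(cls, structure(frames, class = "frame_stream"),
                       seed = 1)
  expect_equal(nrow(s), 10L)
  expect_equal(s$time_s, 0:9)
  expect_true(all(phase_labels()[max.col(
    as.matrix(s[, c("score_ccc", "score_nuclear", "score_other")]))] ==
      "OTHER"))
  # empty stream and ordering errors
  empty <- structure(list(), class = "frame_stream")
  expect_equal(nrow(classify_stream(cls, empty)), 0L)
  bad <- structure(frames[c(2, 1)], class = "frame_stream")
  expect_error(classify_stream(cls, bad), "ordering error")
})
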