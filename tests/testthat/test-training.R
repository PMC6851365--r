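# Training mechanics at toy scale; the full 5-epoch learning demonstration
# lives in the acceptance suite.

tiny_net <- function(seed = 1)
  build_network(c(75, 75, 3), width_mult = 1 / 16,
                inception_counts = c(1, 1, 1), seed = seed)

tiny_frames <- function(seed = 1, secs = 12) {
  tl <- phase_timeline(c("OTHER", "CCC", "OTHER", "NUCLEAR", "OTHER"),
                       c(0, secs, 2 * secs, 3 * secs, 4 * secs),
                       c(secs, 2 * secs, 3 * secs, 4 * secs, 5 * secs) - 1L)
  render_toy_frames(tl, resolution = c(75, 75), seed = seed)
}

test_that("gradients agree with finite differences for every layer type", {
  ns <- asNamespace("phacoseg")
  set.seed(42)
  specs <- list(
    ns$conv_spec(3, 3, 4, stride = 2),
    ns$inception_spec(list(
      list(ns$conv_spec(1, 1, 3)),
      list(ns$conv_spec(1, 1, 2), ns$conv_spec(3, 3, 3, pad = "same")),
      list(ns$avgpool_spec(3, 3, 1, "same"), ns$conv_spec(1, 1, 2)))),
    ns$maxpool_spec(3, 3, 2),
    ns$gap_spec(),
    ns$dense_spec(5),
    ns$dense_spec(3, act = "linear"))
  layers <- ns$init_layers(specs, c(11, 11, 3))$layers
  x <- array(runif(11 * 11 * 3 * 4), c(11, 11, 3, 4))
  y <- c(1L, 2L, 3L, 1L)
  loss_of <- function(l) {
    p <- ns$softmax_cols(ns$net_forward(l, x, training = TRUE)$out)
    -mean(log(p[cbind(y, 1:4)]))
  }
  fwd <- ns$net_forward(layers, x, training = TRUE)
  p <- ns$softmax_cols(fwd$out)
  dz <- p; dz[cbind(y, 1:4)] <- dz[cbind(y, 1:4)] - 1; dz <- dz / 4
  bwd <- ns$net_backward(fwd$layers, fwd$caches, dz)
  eps <- 1e-5
  check <- function(getp, setp, g) {
    pv <- getp(layers)
    for (i in sample(length(pv), min(4, length(pv)))) {
      pp <- pv; pp[i] <- pv[i] + eps
      pm <- pv; pm[i] <- pv[i] - eps
      num <- (loss_of(setp(layers, pp)) - loss_of(setp(layers, pm))) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
  check(function(l) l[[1]]$w, function(l, v) { l[[1]]$w[] <- v; l },
        bwd$layers[[1]]$g_w)
  check(function(l) l[[1]]$gamma, function(l, v) { l[[1]]$gamma <- v; l },
        bwd$layers[[1]]$g_gamma)
  check(function(l) l[[2]]$branches[[2]][[2]]$w,
        function(l, v) { l[[2]]$branches[[2]][[2]]$w[] <- v; l },
        bwd$layers[[2]]$branches[[2]][[2]]$g_w)
  check(function(l) l[[5]]$w, function(l, v) { l[[5]]$w[] <- v; l },
        bwd$layers[[5]]$g_w)
})

test_that("training reduces the loss and is reproducible under a seed", {
  frames <- tiny_frames(seed = 7)
  cfg <- training_config(learning_rate = 0.01, max_epochs = 3, seed = 5,
                         augmentation = no_augmentation())
  n1 <- train_classifier(tiny_net(3), frames, cfg)
  expect_length(n1$loss_log, 3L)
  expect_lt(tail(n1$loss_log, 1), n1$loss_log[1])
  n2 <- train_classifier(tiny_net(3), frames, cfg)
  expect_identical(n1$loss_log, n2$loss_log)
})

test_that("training validates class coverage", {
  frames <- tiny_frames(seed = 8)
  only_other <- Filter(function(f) f$label == "OTHER", frames)
  expect_error(train_classifier(tiny_net(1), only_other, training_config()),
               "training error")
})

test_that("class balancing presents each class at the majority count", {
  ns <- asNamespace("phacoseg")
  y <- c(rep(1L, 10), rep(2L, 100), rep(3L, 100))
  set.seed(1)
  idx <- ns$balanced_indices(y)
  expect_length(idx, 300L)
  expect_equal(as.integer(table(y[idx])), c(100L, 100L, 100L))
  # every original minority sample still appears
  expect_true(all(1:10 %in% idx))
})

test_that("the identity augmentation leaves images untouched", {
  img <- array(runif(20 * 30 * 3), c(20, 30, 3))
  set.seed(2)
  expect_identical(augment_frame(img, no_augmentation()), img)
})

test_that("augmentation respects the configured caps and output range", {
  expect_error(augmentation_config(rotation_deg_max = 120), "caps")
  expect_error(augmentation_config(shift_frac_max = 0.5), "caps")
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  set.seed(3)
  for (k in 1:10) {
    a <- augment_frame(img, augmentation_config())
    expect_equal(dim(a), dim(img))
    expect_true(all(a >= 0 & a <= 1))
  }
})
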