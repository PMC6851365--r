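test_that("zero-variance specs give the deterministic reference timeline", {
  spec <- surgery_spec(duration_means_s = c(120, 42, 60, 133, 179),
                       duration_sds_s = rep(0, 5))
  tl <- simulate_timeline(spec, seed = 1)
  expect_equal(tl$phase, c("OTHER", "CCC", "OTHER", "NUCLEAR", "OTHER"))
  expect_equal(tl[tl$phase == "CCC", c("start_s", "end_s")],
               data.frame(start_s = 120L, end_s = 161L), ignore_attr = TRUE)
  expect_equal(tl[tl$phase == "NUCLEAR", c("start_s", "end_s")],
               data.frame(start_s = 222L, end_s = 354L), ignore_attr = TRUE)
  expect_equal(max(tl$end_s) + 1L, 534L)
  # seed-independent since variance is zero
  expect_equal(as.data.frame(simulate_timeline(spec, seed = 99)),
               as.data.frame(tl))
})

test_that("sampled durations match the truncated-normal mean", {
  spec <- surgery_spec()
  set.seed(31)
  ccc <- vapply(1:1000, function(i) {
    tl <- simulate_timeline(spec)
    r <- tl[tl$phase == "CCC", ]
    r$end_s - r$start_s + 1L
  }, integer(1))
  target <- truncnorm_mean(42, 44, spec$min_duration_s)
  se <- sd(ccc) / sqrt(length(ccc))
  expect_lt(abs(mean(ccc) - target), 3 * se + 0.5)  # +0.5 for rounding
})

test_that("generated timelines always validate and are seed-reproducible", {
  for (k in 1:25) {
    tl <- simulate_timeline(seed = k)
    expect_s3_class(tl, "phase_timeline")   # constructor validates
    expect_equal(tl$phase, c("OTHER", "CCC", "OTHER", "NUCLEAR", "OTHER"))
    expect_true(all(tl$end_s - tl$start_s + 1L >= 5))
  }
  expect_identical(simulate_timeline(seed = 5), simulate_timeline(seed = 5))
})

test_that("invalid specs are rejected", {
  expect_error(surgery_spec(duration_means_s = c(-1, 42, 60, 133, 179),
                            duration_sds_s = rep(1, 5)), "positive")
  expect_error(surgery_spec(min_duration_s = 0), "positive")
})

test_that("toy frames carry one labeled frame per second, reproducibly", {
  tl <- phase_timeline(c("CCC", "NUCLEAR"), c(2, 6), c(4, 9))
  fr <- render_toy_frames(tl, resolution = c(16, 16), seed = 9)
  expect_length(fr, 10L)
  expect_equal(vapply(fr, `[[`, integer(1), "time_s"), 0:9)
  expect_equal(vapply(fr, `[[`, character(1), "label"),
               labels_from_timeline(tl))
  expect_true(all(vapply(fr, function(f)
    all(dim(f$image) == c(16, 16, 3)) && all(f$image >= 0 & f$image <= 1),
    logical(1))))
  fr2 <- render_toy_frames(tl, resolution = c(16, 16), seed = 9)
  expect_identical(fr, fr2)              # bit-identical under the seed
})

test_that("phase hues separate far beyond within-phase noise", {
  tl <- phase_timeline(c("CCC", "NUCLEAR"), c(0, 60), c(49, 119))
  fr <- render_toy_frames(tl, resolution = c(24, 24), seed = 10)
  lab <- vapply(fr, `[[`, character(1), "label")
  feats <- t(vapply(fr, function(f) apply(f$image, 3, mean), numeric(3)))
  centroids <- vapply(phase_labels(), function(l)
    colMeans(feats[lab == l, , drop = FALSE]), numeric(3))
  within_sd <- mean(vapply(phase_labels(), function(l)
    mean(apply(feats[lab == l, , drop = FALSE], 2, sd)), numeric(1)))
  seps <- c(sqrt(sum((centroids[, 1] - centroids[, 2])^2)),
            sqrt(sum((centroids[, 1] - centroids[, 3])^2)),
            sqrt(sum((centroids[, 2] - centroids[, 3])^2)))
  expect_gte(min(seps) / within_sd, 5)
})

test_that("cohorts pair truths with streams deterministically", {
  c1 <- make_test_cohort(4, seed = 6)
  c2 <- make_test_cohort(4, seed = 6)
  expect_identical(c1$truths, c2$truths)
  expect_identical(c1$scores, c2$scores)
  expect_length(c1$truths, 4L)
  for (id in names(c1$truths))
    expect_equal(nrow(c1$scores[[id]]),
                 max(c1$truths[[id]]$end_s) + 1L)
  # round-trip through the on-disk cohort layout
  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  back <- read_cohort(dir)
  expect_equal(names(back$truths), names(c1$truths))
  expect_equal(as.data.frame(back$truths[[2]]),
               as.data.frame(c1$truths[[2]]))
  expect_equal(back$scores[[3]]$score_ccc, c1$scores[[3]]$score_ccc,
               tolerance = 1e-12)
})
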