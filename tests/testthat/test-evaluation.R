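test_that("per-class rates and the weighted mean follow the count identities", {
  set.seed(11)
  for (k in 1:10) {
    counts <- matrix(sample(0:500, 9, replace = TRUE), 3, 3,
                     dimnames = list(truth = phase_labels(),
                                     decided = phase_labels()))
    rep <- asNamespace("phacoseg")$confusion_report(counts)
    expect_equal(rep$per_class_rate,
                 100 * diag(counts) / rowSums(counts), ignore_attr = TRUE)
    # weighted mean rate == count-weighted mean of per-class rates
    expect_equal(rep$weighted_mean_rate,
                 stats::weighted.mean(rep$per_class_rate, rowSums(counts)))
    expect_equal(rep$n_frames, sum(counts))   # conservation
    # invariance under joint relabeling (matrix permutation)
    p <- sample(3)
    rep2 <- asNamespace("phacoseg")$confusion_report(counts[p, p])
    expect_equal(rep2$weighted_mean_rate, rep$weighted_mean_rate)
  }
})

test_that("decisions identical to truth give a diagonal matrix and rates 100", {
  tl <- fixture_timeline()
  d <- data.frame(time_s = 0:119, ave_ccc = 0, ave_nuclear = 0,
                  ave_other = 0, decided_phase = labels_from_timeline(tl))
  rep <- frame_confusion(d, tl)
  expect_true(all(rep$counts[upper.tri(rep$counts)] == 0))
  expect_true(all(rep$counts[lower.tri(rep$counts)] == 0))
  expect_equal(unname(rep$per_class_rate), c(100, 100, 100))
  expect_equal(rep$weighted_mean_rate, 100)
})

test_that("a single misclassified frame lands in the right confusion cell", {
  tl <- phase_timeline(c("CCC", "NUCLEAR"), c(5, 20), c(10, 30))
  d <- data.frame(time_s = 0L, ave_ccc = 1, ave_nuclear = 0, ave_other = 0,
                  decided_phase = "CCC")           # true label: OTHER
  rep <- frame_confusion(d, tl)
  expect_equal(rep$counts["OTHER", "CCC"], 1L)
  expect_equal(sum(rep$counts), 1L)
  expect_equal(unname(rep$per_class_rate["OTHER"]), 0)
  expect_error(frame_confusion(d[0, ], tl), "no decided frames")
})

test_that("boundary errors are zero for a result scored against its truth", {
  tl <- fixture_timeline()
  d <- data.frame(time_s = 0:119, ave_ccc = 0, ave_nuclear = 0,
                  ave_other = 0, decided_phase = labels_from_timeline(tl))
  r <- extract_boundaries(d)
  rep <- boundary_errors(list(r), list(tl))
  expect_equal(unname(rep$mae), c(0, 0, 0, 0))
  expect_equal(rep$overall_mean_mae, 0)
  expect_equal(unname(rep$n_missing), c(0L, 0L, 0L, 0L))
})

test_that("a constant detection delay yields that constant as every error", {
  tl <- fixture_timeline()
  labs <- labels_from_timeline(tl)
  # shift all decisions 2 s late, as the window-5 closed form predicts
  d <- data.frame(time_s = 2:119, ave_ccc = 0, ave_nuclear = 0,
                  ave_other = 0, decided_phase = labs[1:118])
  r <- extract_boundaries(d, "last_detection")
  rep <- boundary_errors(list(r), list(tl))
  expect_equal(unname(rep$mae), c(2, 2, 2, 2))
  expect_equal(rep$overall_mean_mae, 2)
})

test_that("missing boundaries are excluded from the MAE and tallied", {
  tl <- fixture_timeline()
  d <- data.frame(time_s = 4:119, ave_ccc = 0, ave_nuclear = 0,
                  ave_other = 0,
                  decided_phase = ifelse(labels_from_timeline(tl)[5:120] ==
                                           "NUCLEAR", "OTHER",
                                         labels_from_timeline(tl)[5:120]))
  r <- extract_boundaries(d)
  rep <- boundary_errors(list(r), list(tl))
  expect_equal(unname(rep$n_missing), c(0L, 0L, 1L, 1L))
  expect_true(all(is.nan(rep$mae[3:4])))
  expect_equal(unname(rep$mae[1:2]), c(0, 0))
})

test_that("population and sample SDs differ as expected", {
  tl1 <- fixture_timeline("a"); tl2 <- fixture_timeline("b")
  mk <- function(shift, id) {
    labs <- labels_from_timeline(tl1)
    d <- data.frame(time_s = (0:119) + shift, ave_ccc = 0, ave_nuclear = 0,
                    ave_other = 0, decided_phase = labs)
    attr(d, "source_id") <- id
    extract_boundaries(d)
  }
  res <- list(mk(0, "a"), mk(4, "b"))
  pop <- boundary_errors(res, list(tl1, tl2), sd_type = "population")
  sam <- boundary_errors(res, list(tl1, tl2), sd_type = "sample")
  expect_equal(unname(pop$sd[1]), 2)            # errors 0 and 4
  expect_equal(unname(sam$sd[1]), sqrt(8))
})

test_that("mismatched source ids raise a pairing error", {
  tl <- fixture_timeline("a")
  labs <- labels_from_timeline(tl)
  d <- data.frame(time_s = 0:119, ave_ccc = 0, ave_nuclear = 0,
                  ave_other = 0, decided_phase = labs)
  attr(d, "source_id") <- "zzz"
  r <- extract_boundaries(d)
  expect_error(boundary_errors(list(r), list(tl)), "unmatched source_id")
})

test_that("timeline strips have one column per second and aligned rows", {
  tl <- phase_timeline(c("CCC", "NUCLEAR"), c(5, 15), c(9, 24))
  s1 <- timeline_strip(tl)
  expect_equal(nrow(s1), 25L)
  expect_equal(names(s1), c("time_s", "truth"))  # truth-only: single strip
  sc <- simulate_scores(tl, model = identity_confusion(), seed = 2)
  d <- smooth_stream(sc, 5)
  f <- withr::local_tempfile(fileext = ".csv")
  s2 <- timeline_strip(tl, d, out = f)
  expect_true(file.exists(f))
  expect_equal(names(s2), c("time_s", "truth", "determination"))
  expect_true(all(is.na(s2$determination[1:4])))   # warm-up
  # the determination strip is the truth strip delayed by 2 s at transitions
  expect_equal(s2$determination[8:25], s2$truth[6:23])
  long <- boundary_error_long(boundary_errors(
    list(extract_boundaries(d)), list(tl)))
  expect_equal(nrow(long), 4L)
  expect_named(long, c("boundary", "surgery_id", "abs_error_s"))
})
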