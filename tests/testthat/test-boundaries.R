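test_that("both end rules reproduce the worked decision-sequence example", {
  # decided labels at seconds 5..13
  labs <- c("OTHER", "OTHER", "CCC", "CCC", "CCC", "OTHER", "NUCLEAR",
            "NUCLEAR", "OTHER")
  d <- data.frame(time_s = 5:13, ave_ccc = 0, ave_nuclear = 0, ave_other = 0,
                  decided_phase = labs)
  r1 <- extract_boundaries(d, "last_detection")
  expect_equal(r1$ccc_start_s, 7L)
  expect_equal(r1$ccc_end_s, 9L)
  expect_equal(r1$nuclear_start_s, 11L)
  expect_equal(r1$nuclear_end_s, 12L)
  r2 <- extract_boundaries(d, "pre_next_phase")
  expect_equal(r2$ccc_start_s, 7L)
  expect_equal(r2$ccc_end_s, 10L)      # first NUCLEAR decision - 1
  expect_equal(r2$nuclear_start_s, 11L)
  expect_equal(r2$nuclear_end_s, 12L)  # first phase change after start - 1
})

test_that("phases never decided are reported missing", {
  d <- data.frame(time_s = 4:20, ave_ccc = 0, ave_nuclear = 0, ave_other = 1,
                  decided_phase = "OTHER")
  r <- extract_boundaries(d)
  expect_true(is.na(r$ccc_start_s) && is.na(r$ccc_end_s))
  expect_true(is.na(r$nuclear_start_s) && is.na(r$nuclear_end_s))
  expect_error(extract_boundaries(d[0, ]), "non-empty")
})

test_that("a perfect classifier with window 5 detects starts exactly 2 s late", {
  # brute-force enumeration: slide a 5-frame window over a phase change at t;
  # the new phase first reaches >= 3 of 5 one-hot votes at t + 2
  for (prev in c("OTHER", "CCC")) {
    new <- if (prev == "CCC") "NUCLEAR" else "CCC"
    first <- NA
    for (i in 0:6) {                   # decision index relative to change t
      win <- c(rep(prev, max(0, 5 - 1 - i)), rep(new, min(5, i + 1)))
      win <- tail(win, 5)
      votes <- table(factor(win, levels = phase_labels()))
      if (is.na(first) && names(which.max(votes)) == new) first <- i
    }
    expect_equal(first, 2)
  }
  # and end-to-end on simulated surgeries with identity confusion
  tl <- fixture_timeline()
  sc <- simulate_scores(tl, model = identity_confusion(), seed = 9)
  r <- extract_boundaries(smooth_stream(sc, 5), "last_detection")
  expect_equal(r$ccc_start_s, 22L)     # true start 20
  expect_equal(r$ccc_end_s, 41L)       # true end 39
  expect_equal(r$nuclear_start_s, 62L)
  expect_equal(r$nuclear_end_s, 91L)
})

test_that("detected boundaries are ordered whenever present", {
  set.seed(77)
  for (k in 1:20) {
    tl <- simulate_timeline(seed = k)
    sc <- simulate_scores(tl, model = confusion_model(), seed = 1000 + k)
    r <- extract_boundaries(smooth_stream(sc, 5))
    if (!is.na(r$ccc_start_s)) expect_lte(r$ccc_start_s, r$ccc_end_s)
    if (!is.na(r$nuclear_start_s))
      expect_lte(r$nuclear_start_s, r$nuclear_end_s)
  }
})

test_that("segmentation results serialize to JSON with null for missing", {
  d <- data.frame(time_s = 4:20, ave_ccc = 0, ave_nuclear = 0, ave_other = 1,
                  decided_phase = c(rep("OTHER", 5), rep("CCC", 4),
                                    rep("OTHER", 8)))
  r <- extract_boundaries(d)
  f <- withr::local_tempfile(fileext = ".json")
  write_segmentation(r, f)
  txt <- paste(readLines(f), collapse = "")
  expect_match(txt, "null")            # missing nuclear boundary
  r2 <- read_segmentation(f)
  expect_equal(r2$ccc_start_s, r$ccc_start_s)
  expect_true(is.na(r2$nuclear_start_s))
})
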