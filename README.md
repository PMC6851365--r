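# phacoseg

Real-time surgical phase segmentation for cataract surgery video.

`phacoseg` is for researchers in surgical workflow analysis and
ophthalmic-surgery training who need to locate the two highest-stakes
phases of phacoemulsification — the continuous curvilinear capsulorrhexis
(CCC) and nuclear extraction — in video, *as the surgery runs*, and to
score how well an automatic system does so against an ophthalmologist's
annotation.

## The method

Video is sampled at 1 FPS and each frame is classified independently into
{CCC, nuclear extraction, others} by a convolutional network, giving a
per-second score triple. The scores are passed through a trailing 5-frame
moving average

    Ave_i^j = (1/5) * sum_{k=i-4..i} eval_k^j ,   i > 4,

and the decided phase at second *i* is the argmax of the three smoothed
scores (ties broken CCC > NUCLEAR > OTHER). A phase's start time is the
second it is first decided; its end time is the second it is last decided
(`last_detection`, default) or the second before the next phase's first
decision (`pre_next_phase`). Because the window trails, every decision uses
only the last 5 seconds of video — the method is causal and therefore
deployable intra-operatively. The price is a fixed detection lag: with a
perfect frame classifier every boundary is exactly 2 s late.

Evaluation follows the conventions of this task: a per-frame confusion
matrix with per-class correct-response rates and their frame-weighted mean,
and per-boundary absolute errors in seconds summarized by mean (MAE) and
SD.

The package contains the full pipeline — frame ingestion (1 FPS sampling,
bilinear resize to 299×168, [0,1] normalization), a from-scratch
Inception-style CNN with momentum-SGD training (batch norm, inception
branches, class-balanced oversampling, geometric/photometric
augmentation; RcppArmadillo kernels), the streaming smoother and boundary
extractor, the evaluation metrics, and a seeded synthetic-surgery
generator (timelines, confusion-model score streams, rendered toy frames)
so that every stage is testable without clinical video.

## Worked example

Simulate one surgery, classify it with the default per-frame confusion
model (per-class accuracies 90.7 / 94.5 / 97.9 %), smooth, and extract
boundaries:

```r
library(phacoseg)

truth  <- simulate_timeline(surgery_spec(), seed = 7, source_id = "demo")
truth
#> Phase timeline for demo (561 s)
#>     phase start_s end_s
#> 1   OTHER       0   336
#> 2     CCC     337   380
#> 3   OTHER     381   405
#> 4 NUCLEAR     406   443
#> 5   OTHER     444   560

scores    <- simulate_scores(truth, model = confusion_model(), seed = 8)
decisions <- smooth_stream(scores, window_len = 5)
extract_boundaries(decisions, end_rule = "last_detection")
#> Segmentation result (end rule: last_detection )
#>   CCC:     340 s -> 381 s
#>   NUCLEAR: 408 s -> 445 s
```

The CCC truly spans 337–380 s and is detected at 340–381 s: the start is 3 s
late (the 2 s window lag plus one noisy frame) and the end 1 s late. At
cohort scale the pipeline recovers the confusion model it was fed:

```r
cohort <- make_test_cohort(48, seed = 7)
ev <- evaluate_cohort(cohort$truths, cohort$scores, run_config(),
                      confusion_window = 1)   # window 1 = per-frame rates
ev$confusion
#> Correct response rate [%]: CCC 90.0, NUCLEAR 94.8, OTHER 97.8
#> Mean (frame-weighted): 96.4%
ev$boundary
#>         ccc_start ccc_end nuclear_start nuclear_end
#> MAE [s]      2.23    1.69          2.17        1.85
#> Overall mean MAE: 1.98 s
```

The recovered per-class rates sit within sampling error of the simulated
90.7 / 94.5 / 97.9 %, and the boundary MAEs hover around the 2 s window
lag — smoothing absorbs almost all of the per-frame noise at the
boundaries.

A command-line front end covers the same flow
(`inst/cli/phacoseg simulate|segment|evaluate|run`), and
`build_network()` / `train_classifier()` train the Inception-style CNN on
rendered toy frames; see the methods vignette
(`vignettes/phase-segmentation.Rmd`) for the model, the generator's
assumptions, and all numerical choices.

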