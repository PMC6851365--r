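# Shared fixtures, built in code at test time.

# a short, well-separated surgery: OTHER 0-19, CCC 20-39, OTHER 40-59,
# NUCLEAR 60-89, OTHER 90-119
fixture_timeline <- function(id = "fix") {
  phase_timeline(c("OTHER", "CCC", "OTHER", "NUCLEAR", "OTHER"),
                 c(0, 20, 40, 60, 90), c(19, 39, 59, 89, 119),
                 source_id = id)
}

# score stream with a given decided-class sequence, as one-hot triples
onehot_scores <- function(labels, t0 = 0L) {
  n <- length(labels)
  m <- matrix(0, n, 3)
  m[cbind(seq_len(n), match(labels, phase_labels()))] <- 1
  data.frame(time_s = t0 + seq_len(n) - 1L, score_ccc = m[, 1],
             score_nuclear = m[, 2], score_other = m[, 3])
}

random_scores <- function(n, t0 = 0L) {
  m <- matrix(stats::rgamma(3 * n, 1), n, 3)
  m <- m / rowSums(m)
  data.frame(time_s = t0 + seq_len(n) - 1L, score_ccc = m[, 1],
             score_nuclear = m[, 2], score_other = m[, 3])
}

# independent batch oracle for the trailing moving average: recompute every
# window from scratch (no shared state with the streaming implementation)
brute_force_windows <- function(scores, w) {
  n <- nrow(scores)
  if (n < w) return(NULL)
  cols <- c("score_ccc", "score_nuclear", "score_other")
  out <- t(vapply(w:n, function(i)
    colMeans(as.matrix(scores[(i - w + 1):i, cols])), numeric(3)))
  data.frame(time_s = scores$time_s[w:n], ave_ccc = out[, 1],
             ave_nuclear = out[, 2], ave_other = out[, 3])
}

# nearest-centroid classifier on per-frame mean RGB: the independent
# baseline showing toy classes are separable by color
pixel_mean_baseline <- function(train_frames, test_frames) {
  feats <- function(frames)
    t(vapply(frames, function(f) apply(f$image, 3, mean), numeric(3)))
  lab <- vapply(train_frames, `[[`, character(1), "label")
  ft <- feats(train_frames)
  centroids <- do.call(rbind, lapply(phase_labels(), function(l)
    colMeans(ft[lab == l, , drop = FALSE])))
  fx <- feats(test_frames)
  d2 <- vapply(seq_len(nrow(centroids)), function(k)
    rowSums(sweep(fx, 2, centroids[k, ])^2), numeric(nrow(fx)))
  phase_labels()[max.col(-d2)]
}

# closed-form mean of a normal truncated below at a
truncnorm_mean <- function(mu, sd, a) {
  if (sd == 0) return(max(mu, a))
  z <- (a - mu) / sd
  mu + sd * stats::dnorm(z) / (1 - stats::pnorm(z))
}
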