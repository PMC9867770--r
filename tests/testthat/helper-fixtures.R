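# Shared fixtures. Heavy objects (a trained subject suite) are built once per
# test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# Small study profile: short pauses/walks and fewer repetitions -- enough
# structure for mechanics tests (splits still need >= 2 reps per payload).
tiny_study_config <- function(noise_scale = 1) {
  study_config(desk_scale = TRUE, reps_d1 = 4, reps_d2 = 4, reps_d3 = 2,
               noise_scale = noise_scale)
}

# Small but real model configuration for mechanics tests: large enough to
# classify the easy synthetic classes reliably, small enough to train in
# tens of seconds.
tiny_model_config <- function(seed = 1) {
  model_config(recurrent_units = c(12, 6), dense_units = 8,
               max_epochs = 20, patience = 5, seed = seed)
}

# One trained subject (HAR + payload models, FULL_5), memoized.
fixture_suite <- function() {
  if (!is.null(.fixture_cache$suite)) return(.fixture_cache$suite)
  bundle <- generate_subject(42, tiny_study_config())
  suite <- train_subject_suite(bundle, configs = "FULL_5",
                               model_cfg = tiny_model_config(),
                               train_stride = 6, split_seed = 1)
  .fixture_cache$suite <- list(bundle = bundle, suite = suite$FULL_5)
  .fixture_cache$suite
}

# A short labeled recording for IO / gating tests.
fixture_recording <- function(seed = 3, noise_scale = 1) {
  profile <- make_subject_profile(seed)
  script <- script_protocol2(10, reps = 2, stand = 2, walk = 2)
  render_recording(profile, script, fs = 100, seed = seed,
                   noise_scale = noise_scale)
}

# Random label vectors over a vocabulary.
random_labels <- function(n, classes, seed) {
  withr::with_seed(seed, sample(classes, n, replace = TRUE))
}

# Independent brute-force confusion tally (double loop; the package path
# uses table()).
oracle_confusion <- function(y_true, y_pred, classes) {
  out <- data.frame(class = as.character(classes), TP = 0L, FP = 0L,
                    TN = 0L, FN = 0L, support = 0L,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(classes)) {
    c <- classes[ci]
    for (i in seq_along(y_true)) {
      t_is <- y_true[i] == c
      p_is <- y_pred[i] == c
      if (t_is && p_is) out$TP[ci] <- out$TP[ci] + 1L
      else if (!t_is && p_is) out$FP[ci] <- out$FP[ci] + 1L
      else if (t_is && !p_is) out$FN[ci] <- out$FN[ci] + 1L
      else out$TN[ci] <- out$TN[ci] + 1L
      if (t_is) out$support[ci] <- out$support[ci] + (i == i)
    }
  }
  out$support <- vapply(classes, function(c) sum(y_true == c), integer(1))
  out
}

# Independent quartiles: sort and linearly interpolate order statistics.
oracle_quartiles <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}
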