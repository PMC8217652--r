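# Fixtures built in code: a minimal OpenFace-style frame table, small
# cohorts, and a well-separated frame dataset for classifier sanity checks.

# Frame table with all required columns; AU channels default to zero and can
# be overridden via `aus`, a named list like list(AU20_r = ..., AU20_c = ...).
make_frames <- function(n, aus = list(), frame_rate = 30) {
  f <- data.frame(frame = seq_len(n), timestamp = (seq_len(n) - 1) / frame_rate,
                  confidence = 0.95, success = 1)
  for (i in 0:67) {
    f[[paste0("x_", i)]] <- rep(100 + i, n)
    f[[paste0("y_", i)]] <- rep(80 + i, n)
  }
  for (au in fearleak::FEAR_AUS_7) {
    f[[paste0("AU", au, "_r")]] <- rep(0, n)
    f[[paste0("AU", au, "_c")]] <- rep(0, n)
  }
  for (nm in names(aus)) f[[nm]] <- aus[[nm]]
  f
}

make_clip <- function(n = 10, participant = "P01", condition = "truth",
                      aus = list(), frame_rate = 30) {
  clip_timeseries(make_frames(n, aus, frame_rate), participant, condition,
                  frame_rate)
}

# Cached small synthetic cohort shared across test files.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_spec(n_participants = 6,
                                            truth_clip_seconds = 15,
                                            lie_clip_seconds = 6,
                                            seed = 11))
    cache
  }
})

# Frame dataset with strong class separation and balanced classes per
# participant, for classifier benchmarks.
make_separable_dataset <- function(n_participants = 16, per_class = 40,
                                   shift = 4, seed = 99) {
  set.seed(seed)
  p <- 7
  rows <- n_participants * 2 * per_class
  features <- matrix(rnorm(rows * p), rows, p,
                     dimnames = list(NULL, paste0("AU", fearleak::FEAR_AUS_7)))
  labels <- factor(rep(rep(c("lie", "truth"), each = per_class),
                       n_participants), levels = c("lie", "truth"))
  features[labels == "lie", 1:2] <- features[labels == "lie", 1:2] + shift
  groups <- rep(sprintf("P%02d", seq_len(n_participants)),
                each = 2 * per_class)
  fearleak:::new_frame_dataset(features, labels, groups)
}
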