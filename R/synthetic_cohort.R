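## Synthetic cohort generator: OpenFace-format clips with the statistical
## structure the downstream analysis assumes (paired truth/lie clips of very
## unequal length, sparse AU episodes with group-specific decay, left/right
## distance signals with controllable coupling).

#' Specify a synthetic cohort
#'
#' Defaults emulate the published game-show material: 16 participants, one
#' merged truth clip (mean 105.5 s) and one lie clip (mean 7.8 s) each at
#' 30 f/s, and AU episodes whose apex-to-offset (decay) phase is shorter in
#' the lie condition (means 11.35 vs 6.98 frames). Phase durations are gamma
#' distributed (positive, right-skewed); clip lengths are gamma distributed
#' around the group means with a 3 s floor.
#'
#' @param n_participants number of participants (two clips each).
#' @param truth_clip_seconds,lie_clip_seconds mean clip durations in seconds.
#' @param frame_rate frames per second.
#' @param episode_rate expected AU episodes per minute per AU channel.
#' @param rise_frames list `(mean, shape)` of the gamma onset-to-apex
#'   duration (frames), shared between groups.
#' @param decay_frames_truth,decay_frames_lie list `(mean, shape)` of the
#'   gamma apex-to-offset duration per group.
#' @param peak_intensity list `(shape1, shape2)`; peaks are
#'   `0.5 + 4.5 * Beta(shape1, shape2)` so every episode has positive score.
#' @param asym_lag_truth,asym_lag_lie left-right lag in frames of the right
#'   distance signal relative to the left.
#' @param asym_noise_truth,asym_noise_lie mixing weight in \[0, 1\] of
#'   independent noise in the right distance signal (0 = fully coupled).
#' @param base_waveform list `(baseline, amplitude, smooth_sd)` of the
#'   eyebrow-eye distance fluctuation (pixels; Gaussian-smoothed noise).
#' @param clip_seconds_shape gamma shape of the clip-length distribution.
#' @param landmark_jitter isotropic jitter (pixels) on non-target landmarks.
#' @param seed integer seed; `generate_cohort()` is fully reproducible.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 16,
                        truth_clip_seconds = 105.5,
                        lie_clip_seconds = 7.8,
                        frame_rate = 30,
                        episode_rate = 24,
                        rise_frames = list(mean = 9.42, shape = 4),
                        decay_frames_truth = list(mean = 11.35, shape = 4),
                        decay_frames_lie = list(mean = 6.98, shape = 4),
                        peak_intensity = list(shape1 = 2, shape2 = 2),
                        asym_lag_truth = 1,
                        asym_lag_lie = 3,
                        asym_noise_truth = 0.25,
                        asym_noise_lie = 0.55,
                        base_waveform = list(baseline = 30, amplitude = 3,
                                             smooth_sd = 5),
                        clip_seconds_shape = 4,
                        landmark_jitter = 0.05,
                        seed = 20210608) {
  spec <- as.list(environment())
  pos <- c(n_participants = n_participants,
           truth_clip_seconds = truth_clip_seconds,
           lie_clip_seconds = lie_clip_seconds, frame_rate = frame_rate,
           episode_rate = episode_rate, rise = rise_frames$mean,
           decay_truth = decay_frames_truth$mean,
           decay_lie = decay_frames_lie$mean)
  if (any(!is.finite(pos)) || any(pos <= 0))
    fl_stop("InvalidSpec", "durations, rates and counts must be > 0")
  w <- c(asym_noise_truth, asym_noise_lie)
  if (any(w < 0 | w > 1))
    fl_stop("InvalidSpec", "noise mixing weights must lie in [0, 1]")
  class(spec) <- "cohort_spec"
  spec
}

## Fixed template face: 68 landmarks on a schematic oval. Only landmarks
## 20/40 and 25/43 (0-based) carry signal; the rest are scenery.
landmark_template <- function() {
  th <- seq(0, 2 * pi, length.out = 69)[1:68]
  cbind(x = 120 + 55 * cos(th), y = 120 + 70 * sin(th))
}

#' Inject one AU episode into a score channel
#'
#' Writes a triangular onset-apex-offset activation: the score ramps linearly
#' up over `rise` frames to `peak` (apex at `onset + rise - 1`), then decays
#' over `decay` frames, staying strictly positive until the offset frame
#' `onset + rise + decay - 1`. Frames outside the episode are untouched.
#'
#' @param channel numeric vector of per-frame AU scores (0 = absent).
#' @param onset 1-based onset frame.
#' @param rise,decay phase lengths in frames (each >= 1).
#' @param peak apex score in (0, 5].
#' @return The modified channel.
#' @export
inject_episode <- function(channel, onset, rise, decay, peak) {
  stopifnot(is.numeric(channel), rise >= 1, decay >= 1, peak > 0)
  len <- rise + decay
  if (onset < 1 || onset + len - 1 > length(channel))
    fl_stop("OutOfBounds", "episode [%d, %d] outside channel of length %d",
            onset, onset + len - 1, length(channel))
  up <- peak * seq_len(rise) / rise
  down <- peak * (1 - seq_len(decay) / (decay + 1))
  channel[onset:(onset + len - 1)] <- c(up, down)
  channel
}

#' Generate coupled left/right distance signals
#'
#' The left series is baseline plus Gaussian-smoothed noise; the right series
#' is the left delayed by `lag` frames and mixed with an independent copy of
#' the same process at weight `noise_weight` (0 gives a pure delayed copy,
#' 1 gives an independent signal). These are the synthetic stand-ins for the
#' left/right eyebrow-eye distances whose wavelet coherence measures facial
#' asymmetry.
#'
#' @param n_frames series length (> 64, the minimum for the coherence
#'   transform).
#' @param base_waveform list `(baseline, amplitude, smooth_sd)`.
#' @param lag delay of the right series in frames (>= 0).
#' @param noise_weight independent-noise mixing weight in \[0, 1\].
#' @param seed optional integer seed.
#' @return List with numeric vectors `left` and `right`.
#' @export
generate_distance_signals <- function(n_frames,
                                      base_waveform = list(baseline = 30,
                                                           amplitude = 3,
                                                           smooth_sd = 5),
                                      lag = 0, noise_weight = 0,
                                      seed = NULL) {
  if (n_frames <= 64) fl_stop("InvalidSpec", "n_frames must be > 64")
  if (noise_weight < 0 || noise_weight > 1)
    fl_stop("InvalidSpec", "noise_weight must lie in [0, 1]")
  if (lag < 0 || lag >= n_frames)
    fl_stop("InvalidSpec", "lag must lie in [0, n_frames)")
  if (!is.null(seed)) set.seed(seed)
  lag <- as.integer(round(lag))
  base <- smoothed_noise(n_frames + lag, base_waveform$smooth_sd)
  left <- base[(lag + 1):(lag + n_frames)]
  delayed <- base[1:n_frames]
  noise <- smoothed_noise(n_frames, base_waveform$smooth_sd)
  w <- noise_weight
  rightf <- (1 - w) * delayed + w * noise
  list(left = base_waveform$baseline + base_waveform$amplitude * left,
       right = base_waveform$baseline + base_waveform$amplitude * rightf)
}

## Unit-variance Gaussian-smoothed white noise.
smoothed_noise <- function(n, smooth_sd) {
  half <- max(1L, ceiling(3 * smooth_sd))
  kern <- dnorm(seq(-half, half), sd = smooth_sd)
  kern <- kern / sum(kern)
  raw <- rnorm(n + 2 * half)
  sm <- stats::filter(raw, kern, sides = 2)[(half + 1):(half + n)]
  sm <- as.numeric(sm)
  (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic cohort of truth/lie clip pairs
#'
#' Produces exactly two clips per participant (one truth, one lie) in the
#' OpenFace dialect: sparse fear-AU episodes with group-specific decay are
#' injected into the AU channels, and the left/right eyebrow-eye distance
#' signals are embedded exactly into landmarks 20/40 and 25/43 so the
#' symmetry module reconstructs them. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List of `clip_ts` objects (length `2 * n_participants`), truth
#'   and lie clip for participant 1, then participant 2, and so on.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)
  clips <- vector("list", 2L * spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    pid <- sprintf("P%02d", i)
    clips[[2L * i - 1L]] <- synth_clip(spec, pid, "truth")
    clips[[2L * i]] <- synth_clip(spec, pid, "lie")
  }
  clips
}

synth_clip <- function(spec, pid, condition) {
  fr <- spec$frame_rate
  mean_sec <- if (condition == "truth") spec$truth_clip_seconds
              else spec$lie_clip_seconds
  sh <- spec$clip_seconds_shape
  sec <- max(3, rgamma(1, shape = sh, scale = mean_sec / sh))
  n <- max(90L, as.integer(round(sec * fr)))

  decay_par <- if (condition == "truth") spec$decay_frames_truth
               else spec$decay_frames_lie
  lag <- if (condition == "truth") spec$asym_lag_truth else spec$asym_lag_lie
  w <- if (condition == "truth") spec$asym_noise_truth else spec$asym_noise_lie

  ds <- generate_distance_signals(n, spec$base_waveform, lag, w)

  tmpl <- landmark_template()
  X <- matrix(rep(tmpl[, 1], each = n), nrow = n) +
    matrix(rnorm(n * 68, sd = spec$landmark_jitter), nrow = n)
  Y <- matrix(rep(tmpl[, 2], each = n), nrow = n) +
    matrix(rnorm(n * 68, sd = spec$landmark_jitter), nrow = n)
  ## exact embedding of the distance pair (0-based landmark ids 20/40, 25/43)
  X[, 21] <- 60; X[, 41] <- 60
  Y[, 21] <- 50; Y[, 41] <- 50 + ds$left
  X[, 26] <- 140; X[, 44] <- 140
  Y[, 26] <- 50; Y[, 44] <- 50 + ds$right

  frames <- data.frame(frame = seq_len(n), timestamp = (seq_len(n) - 1) / fr,
                       confidence = 0.98, success = 1)
  frames[paste0("x_", 0:67)] <- X
  frames[paste0("y_", 0:67)] <- Y

  minutes <- n / fr / 60
  occupied <- rep(FALSE, n)
  for (au in FEAR_AUS_7) {
    chan <- numeric(n)
    n_ep <- rpois(1, spec$episode_rate * minutes)
    for (k in seq_len(n_ep)) {
      rise <- max(1L, as.integer(round(rgamma(1, spec$rise_frames$shape,
        scale = spec$rise_frames$mean / spec$rise_frames$shape))))
      decay <- max(1L, as.integer(round(rgamma(1, decay_par$shape,
        scale = decay_par$mean / decay_par$shape))))
      len <- rise + decay
      if (len + 2L > n) next
      peak <- 0.5 + 4.5 * rbeta(1, spec$peak_intensity$shape1,
                                spec$peak_intensity$shape2)
      for (try in 1:50) {
        onset <- sample.int(n - len + 1L, 1L)
        span <- max(1L, onset - 1L):min(n, onset + len)
        if (!any(occupied[span])) {
          chan <- inject_episode(chan, onset, rise, decay, peak)
          occupied[onset:(onset + len - 1L)] <- TRUE
          break
        }
      }
    }
    occupied[] <- FALSE
    frames[[paste0("AU", au, "_r")]] <- pmin(chan, 5)
    frames[[paste0("AU", au, "_c")]] <- as.numeric(chan > 0)
  }
  clip_timeseries(frames, pid, condition, fr)
}

#' Write a cohort to disk as OpenFace CSVs plus a manifest
#'
#' @param clips list of `clip_ts` objects.
#' @param dir output directory (created if absent).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(clips, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(clips, function(cl) {
    fname <- sprintf("%s_%s.csv", cl$participant_id, cl$condition)
    write_frame_table(cl, file.path(dir, fname))
    data.frame(path = fname, participant_id = cl$participant_id,
               condition = cl$condition, frame_rate = cl$frame_rate)
  })
  man <- do.call(rbind, rows)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}
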