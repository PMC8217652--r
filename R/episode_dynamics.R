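## Segmentation of AU activations into onset/apex/offset episodes, duration
## decomposition, ms conversion, and micro/macro expression counting.

#' Segment a score series into AU episodes
#'
#' Episodes are maximal runs of positive score. Within a run the apex is the
#' frame of maximum score (earliest frame on ties). The phase convention is
#' additive: onset-to-apex counts frames `[onset..apex]` (apex included),
#' apex-to-offset counts `(apex..offset]`, so the two phases always sum to
#' the total duration `offset - onset + 1`.
#'
#' @param scores numeric vector of non-negative per-frame scores
#'   (0 = absent), e.g. one column of [fear_matrix()].
#' @param au_id optional AU label attached to each episode.
#' @return data.frame with one row per episode: `au`, `onset_frame`,
#'   `apex_frame`, `offset_frame`, `total_frames`, `onset_to_apex_frames`,
#'   `apex_to_offset_frames`, `peak_score`. Zero rows on all-zero input.
#' @export
segment_episodes <- function(scores, au_id = NA_character_) {
  stopifnot(is.numeric(scores))
  if (any(scores < 0)) fl_stop("OutOfRange", "scores must be non-negative")
  r <- rle(scores > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts))
    return(data.frame(au = character(), onset_frame = integer(),
                      apex_frame = integer(), offset_frame = integer(),
                      total_frames = integer(),
                      onset_to_apex_frames = integer(),
                      apex_to_offset_frames = integer(),
                      peak_score = numeric(), stringsAsFactors = FALSE))
  apex <- mapply(function(s, e) s + which.max(scores[s:e]) - 1L, starts, ends)
  peak <- scores[apex]
  data.frame(au = au_id, onset_frame = as.integer(starts),
             apex_frame = as.integer(apex), offset_frame = as.integer(ends),
             total_frames = as.integer(ends - starts + 1L),
             onset_to_apex_frames = as.integer(apex - starts + 1L),
             apex_to_offset_frames = as.integer(ends - apex),
             peak_score = peak, stringsAsFactors = FALSE)
}

#' Convert a frame count to milliseconds
#'
#' `frames / frame_rate * 1000`. No rounding is applied here; round only at
#' report time (e.g. 20.77 frames at 30 f/s is 692 ms after rounding).
#'
#' @param frames frame count (may be fractional, e.g. a mean duration).
#' @param frame_rate frames per second (> 0).
#' @return Duration in milliseconds.
#' @export
frames_to_ms <- function(frames, frame_rate = 30) {
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    fl_stop("NonPositiveRate", "frame_rate must be > 0")
  frames / frame_rate * 1000
}

#' Episode table for a whole cohort
#'
#' Runs [segment_episodes()] on the fear score channel of one AU for every
#' clip and returns a tidy table.
#'
#' @param clips list of `clip_ts` objects.
#' @param au AU id (default `"20"`, the lip stretcher central to leaked
#'   fear).
#' @return data.frame: `participant_id`, `condition`, episode fields of
#'   [segment_episodes()], and `total_ms`.
#' @export
cohort_episodes <- function(clips, au = "20") {
  rows <- lapply(clips, function(cl) {
    sc <- fear_matrix(cl, au)[, 1]
    ep <- segment_episodes(sc, au_id = paste0("AU", au))
    if (nrow(ep) == 0L) return(NULL)
    cbind(data.frame(participant_id = cl$participant_id,
                     condition = cl$condition, stringsAsFactors = FALSE),
          ep, total_ms = frames_to_ms(ep$total_frames, cl$frame_rate))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Summarise episode durations
#'
#' Mean, median and a percentile-bootstrap 95% CI of the total duration, the
#' mean apex-to-offset (decay) duration, and counts of episodes at or below
#' the micro- and macro-expression thresholds. Thresholds in ms are converted
#' to frames as `floor(ms * frame_rate / 1000)` (200 ms at 30 f/s is 6
#' frames, 500 ms is 15 frames).
#'
#' @param episodes data.frame from [segment_episodes()] or
#'   [cohort_episodes()].
#' @param frame_rate frames per second.
#' @param micro_ms,macro_ms duration thresholds in milliseconds.
#' @param n_boot bootstrap iterations for the CI of the mean total duration.
#' @param seed integer seed for the bootstrap.
#' @return List of class `duration_summary`.
#' @export
duration_summary <- function(episodes, frame_rate = 30, micro_ms = 200,
                             macro_ms = 500, n_boot = 1000, seed = 1L) {
  if (is.null(episodes) || nrow(episodes) == 0L)
    fl_stop("EmptyEpisodeList", "no episodes to summarise")
  tot <- episodes$total_frames
  micro_f <- floor(micro_ms * frame_rate / 1000)
  macro_f <- floor(macro_ms * frame_rate / 1000)
  set.seed(seed)
  boot <- replicate(n_boot, mean(sample(tot, replace = TRUE)))
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  structure(list(n_episodes = nrow(episodes),
                 mean_total_frames = mean(tot),
                 median_total_frames = median(tot),
                 ci_low_frames = ci[1], ci_high_frames = ci[2],
                 mean_apex_to_offset_frames =
                   mean(episodes$apex_to_offset_frames),
                 mean_onset_to_apex_frames =
                   mean(episodes$onset_to_apex_frames),
                 mean_total_ms = frames_to_ms(mean(tot), frame_rate),
                 micro_threshold_frames = micro_f,
                 macro_threshold_frames = macro_f,
                 n_micro = sum(tot <= micro_f),
                 n_macro = sum(tot <= macro_f),
                 frame_rate = frame_rate),
            class = "duration_summary")
}

#' @export
print.duration_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<duration_summary> %d episodes\n",
    "  total: mean %.2f frames (%.0f ms), median %g, 95%% CI [%.2f, %.2f]\n",
    "  phases: onset-to-apex %.2f, apex-to-offset %.2f frames\n",
    "  <= %d frames (micro): %d; <= %d frames (macro): %d\n"),
    x$n_episodes, x$mean_total_frames, round(x$mean_total_ms),
    x$median_total_frames, x$ci_low_frames, x$ci_high_frames,
    x$mean_onset_to_apex_frames, x$mean_apex_to_offset_frames,
    x$micro_threshold_frames, x$n_micro,
    x$macro_threshold_frames, x$n_macro))
  invisible(x)
}
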