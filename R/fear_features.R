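## Per-frame fear-AU scoring and per-clip AU summaries.

#' Fear-AU score of one frame and channel
#'
#' The score is presence (0/1) multiplied by intensity (0--5): an AU
#' contributes only when the detector marks it present, and then with its
#' estimated intensity.
#'
#' @param presence 0/1 presence value(s).
#' @param intensity intensity value(s) in \[0, 5\].
#' @return `presence * intensity`, in \[0, 5\]. Vectorised.
#' @export
fear_score <- function(presence, intensity) {
  if (any(!presence %in% c(0, 1)))
    fl_stop("OutOfRange", "presence must be 0 or 1")
  if (any(intensity < 0 | intensity > 5))
    fl_stop("OutOfRange", "intensity must lie in [0, 5]")
  presence * intensity
}

#' Per-frame fear feature matrix of a clip
#'
#' @param clip a [clip_timeseries()].
#' @param au_set AU ids forming the feature vector, in order (default the
#'   seven-AU set used by the classifier).
#' @return Numeric matrix (frames x AUs) of fear scores, columns named
#'   `AU<id>`.
#' @export
fear_matrix <- function(clip, au_set = FEAR_AUS_7) {
  stopifnot(inherits(clip, "clip_ts"))
  rcols <- paste0("AU", au_set, "_r")
  ccols <- paste0("AU", au_set, "_c")
  missing <- setdiff(c(rcols, ccols), names(clip$frames))
  if (length(missing))
    fl_stop("MissingChannel", "clip lacks channel(s): %s",
            paste(missing, collapse = ", "))
  m <- as.matrix(clip$frames[rcols]) * as.matrix(clip$frames[ccols])
  colnames(m) <- paste0("AU", au_set)
  m
}

#' Fear feature vector of a single frame
#'
#' @param clip a [clip_timeseries()].
#' @param i frame row index.
#' @inheritParams fear_matrix
#' @return Named numeric vector of length `length(au_set)`.
#' @export
frame_feature_vector <- function(clip, i, au_set = FEAR_AUS_7) {
  m <- fear_matrix(clip, au_set)
  if (i < 1 || i > nrow(m)) fl_stop("OutOfRange", "no frame %d", i)
  m[i, ]
}

#' Per-clip mean AU scores
#'
#' The statistical analysis works on one value per AU per clip: the
#' arithmetic mean of the per-frame fear score over all frames of the clip.
#'
#' @inheritParams fear_matrix
#' @param drop_failed if `TRUE`, frames with `success == 0` are excluded
#'   from the average (the default keeps them, matching the published
#'   processing which applies no such filter).
#' @return One-row data.frame: `participant_id`, `condition`, `n_frames`,
#'   then one `AU<id>` column per AU.
#' @export
clip_mean_aus <- function(clip, au_set = FEAR_AUS_7, drop_failed = FALSE) {
  m <- fear_matrix(clip, au_set)
  if (drop_failed) m <- m[clip$frames$success != 0, , drop = FALSE]
  if (nrow(m) == 0L) fl_stop("EmptyClip", "no frames to average")
  out <- data.frame(participant_id = clip$participant_id,
                    condition = clip$condition, n_frames = nrow(m),
                    stringsAsFactors = FALSE)
  out[colnames(m)] <- as.list(colMeans(m))
  out
}

#' Cohort-level AU summary table
#'
#' @param clips list of `clip_ts` objects.
#' @inheritParams clip_mean_aus
#' @return data.frame with one row per clip (see [clip_mean_aus()]).
#' @export
cohort_mean_aus <- function(clips, au_set = FEAR_AUS_7, drop_failed = FALSE) {
  do.call(rbind, lapply(clips, clip_mean_aus, au_set = au_set,
                        drop_failed = drop_failed))
}
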