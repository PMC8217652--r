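## Reading/writing per-frame facial-feature tables in the OpenFace 2.x CSV
## dialect and assembling them into clip time series.

#' Construct a clip time series
#'
#' A `clip_ts` holds the ordered per-frame records of one video clip for one
#' participant in one condition (truth or lie): frame index, timestamp,
#' tracking success/confidence, the 68 2-D landmarks and the AU intensity
#' (`AUxx_r`, 0--5) and presence (`AUxx_c`, 0/1) channels.
#'
#' @param frames data.frame with columns `frame`, `timestamp`, `confidence`,
#'   `success`, `x_0`..`x_67`, `y_0`..`y_67` and `AUxx_r`/`AUxx_c` for each AU
#'   in `au_set`.
#' @param participant_id participant label.
#' @param condition `"truth"` or `"lie"`.
#' @param frame_rate frames per second (default 30, the common video rate).
#' @param au_set character vector of zero-padded AU ids carried by the clip.
#' @return An object of class `clip_ts`.
#' @export
clip_timeseries <- function(frames, participant_id, condition,
                            frame_rate = 30, au_set = FEAR_AUS_7) {
  condition <- match.arg(condition, c("truth", "lie"))
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    fl_stop("InvalidSpec", "frame_rate must be > 0")
  frames <- as.data.frame(frames)
  if (nrow(frames) == 0L) fl_stop("EmptyTable", "clip has no frames")
  need <- openface_columns(au_set)
  missing <- setdiff(need, names(frames))
  if (length(missing))
    fl_stop("MissingColumn", "missing column(s): %s",
            paste(missing, collapse = ", "))
  frames <- frames[, need, drop = FALSE]
  bad <- !vapply(frames, is.numeric, logical(1))
  if (any(bad))
    fl_stop("MalformedRow", "non-numeric column(s): %s",
            paste(names(frames)[bad], collapse = ", "))
  if (anyNA(frames))
    fl_stop("MalformedRow", "non-numeric or missing cells in %d row(s)",
            sum(!complete.cases(frames)))
  if (nrow(frames) > 1L && any(diff(frames$frame) <= 0))
    fl_stop("MalformedRow", "frame indices must be strictly increasing")
  rcols <- paste0("AU", au_set, "_r")
  ccols <- paste0("AU", au_set, "_c")
  rmat <- as.matrix(frames[rcols])
  cmat <- as.matrix(frames[ccols])
  if (any(rmat < 0 | rmat > 5))
    fl_stop("MalformedRow", "AU intensities outside [0, 5]")
  if (!all(cmat %in% c(0, 1)))
    fl_stop("MalformedRow", "AU presence values must be 0/1")
  structure(list(participant_id = as.character(participant_id),
                 condition = condition,
                 frame_rate = frame_rate,
                 au_set = au_set,
                 frames = frames),
            class = "clip_ts")
}

#' @export
print.clip_ts <- function(x, ...) {
  cat(sprintf("<clip_ts> participant %s, %s, %d frames @ %g f/s (%.1f s)\n",
              x$participant_id, x$condition, nrow(x$frames), x$frame_rate,
              nrow(x$frames) / x$frame_rate))
  invisible(x)
}

#' @export
length.clip_ts <- function(x) nrow(x$frames)

## Required column names for a given AU set (OpenFace naming).
openface_columns <- function(au_set = FEAR_AUS_7) {
  c("frame", "timestamp", "confidence", "success",
    paste0("x_", 0:67), paste0("y_", 0:67),
    paste0("AU", au_set, "_r"), paste0("AU", au_set, "_c"))
}

#' Read an OpenFace-dialect frame table
#'
#' Parses a comma-separated per-frame table as written by OpenFace 2.x. The
#' upstream tool pads header names with spaces (`", AU01_r"`), so headers are
#' matched after trimming surrounding whitespace. Frames with `success = 0`
#' are retained by default; downstream modules decide how to handle them.
#'
#' @param path path to the CSV file.
#' @inheritParams clip_timeseries
#' @param drop_failed if `TRUE`, drop rows with `success == 0` after reading.
#' @return A [clip_timeseries()] object.
#' @export
read_frame_table <- function(path, participant_id, condition,
                             frame_rate = 30, au_set = FEAR_AUS_7,
                             drop_failed = FALSE) {
  if (!file.exists(path)) fl_stop("IOFailure", "no such file: %s", path)
  tab <- data.table::fread(path, sep = ",", header = TRUE,
                           data.table = FALSE, strip.white = TRUE)
  names(tab) <- trimws(names(tab))
  if (nrow(tab) == 0L) fl_stop("EmptyTable", "empty table: %s", path)
  need <- openface_columns(au_set)
  missing <- setdiff(need, names(tab))
  if (length(missing))
    fl_stop("MissingColumn", "%s: missing column(s): %s", path,
            paste(missing, collapse = ", "))
  tab <- tab[need]
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      v <- suppressWarnings(as.numeric(tab[[j]]))
      if (anyNA(v))
        fl_stop("MalformedRow", "%s: non-numeric cell(s) in column %s",
                path, names(tab)[j])
      tab[[j]] <- v
    }
  }
  if (drop_failed) {
    tab <- tab[tab$success != 0, , drop = FALSE]
    if (nrow(tab) == 0L) fl_stop("EmptyTable", "all frames failed: %s", path)
  }
  clip_timeseries(tab, participant_id, condition, frame_rate, au_set)
}

#' Write a clip time series as an OpenFace-dialect CSV
#'
#' The emitted table round-trips through [read_frame_table()]: all numeric
#' fields are reproduced to the serialised precision (15 significant digits).
#'
#' @param clip a [clip_timeseries()] object.
#' @param path destination file.
#' @export
write_frame_table <- function(clip, path) {
  stopifnot(inherits(clip, "clip_ts"))
  data.table::fwrite(clip$frames, path, sep = ",", row.names = FALSE)
  invisible(path)
}

#' Merge clips of one participant and condition
#'
#' Concatenates the records of several clips (e.g. all truth-telling answers
#' of one contestant) into a single clip; frame indices are renumbered
#' consecutively from 1 and timestamps rebuilt from the frame rate.
#'
#' @param clips list of [clip_timeseries()] objects sharing participant,
#'   condition and frame rate.
#' @return A single merged `clip_ts`.
#' @export
merge_clips <- function(clips) {
  if (inherits(clips, "clip_ts")) clips <- list(clips)
  if (length(clips) < 1L) fl_stop("EmptyTable", "no clips to merge")
  stopifnot(all(vapply(clips, inherits, logical(1), "clip_ts")))
  ref <- clips[[1L]]
  same <- vapply(clips, function(cl)
    identical(cl$participant_id, ref$participant_id) &&
      identical(cl$condition, ref$condition) &&
      isTRUE(all.equal(cl$frame_rate, ref$frame_rate)), logical(1))
  if (!all(same))
    fl_stop("MixedIdentity",
            "clips differ in participant, condition or frame rate")
  frames <- do.call(rbind, lapply(clips, `[[`, "frames"))
  frames$frame <- seq_len(nrow(frames))
  frames$timestamp <- (frames$frame - 1) / ref$frame_rate
  clip_timeseries(frames, ref$participant_id, ref$condition,
                  ref$frame_rate, ref$au_set)
}

#' Read a clip manifest
#'
#' A manifest is a CSV with one row per clip file: `path`, `participant_id`,
#' `condition`, `frame_rate`. Paths are resolved relative to the manifest.
#'
#' @param path manifest file.
#' @param au_set AU ids to require in each clip.
#' @param merge if `TRUE` (default), clips sharing participant and condition
#'   are merged with [merge_clips()].
#' @return List of `clip_ts` objects.
#' @export
read_manifest <- function(path, au_set = FEAR_AUS_7, merge = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "participant_id", "condition", "frame_rate")
  if (!all(need %in% names(man)))
    fl_stop("MissingColumn", "manifest needs columns: %s",
            paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  clips <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_frame_table(p, man$participant_id[i], man$condition[i],
                     man$frame_rate[i], au_set)
  })
  if (!merge) return(clips)
  key <- vapply(clips, function(cl)
    paste(cl$participant_id, cl$condition, sep = "\r"), character(1))
  unname(lapply(split(clips, key), merge_clips))
}
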