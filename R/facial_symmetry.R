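## Left/right eyebrow-eye distance signals and their magnitude-squared
## wavelet coherence (analytic Morlet, omega0 = 6, Torrence-Webster
## smoothing), summarised per clip as mean in-cone coherence.

#' Left/right eyebrow-eye distance signals of a clip
#'
#' Per-frame Euclidean distances between the left eyebrow and left eye
#' (landmarks 20 and 40) and between the right eyebrow and right eye
#' (landmarks 25 and 43), in the 0-based indexing of the 68-point scheme
#' used by OpenFace. These two signals track the vertical movement of each
#' eyebrow; their coherence measures left/right facial symmetry.
#'
#' @param clip a [clip_timeseries()].
#' @param index_base 0 (upstream tool convention, default) or 1; a 1-based
#'   reading shifts all four landmark indices.
#' @param interpolate_failed linearly interpolate frames with
#'   `success == 0` (the coherence transform needs gap-free input).
#' @return List `ld1`, `rd1` (numeric vectors) and `frame_rate`.
#' @export
distance_signals <- function(clip, index_base = 0,
                             interpolate_failed = TRUE) {
  stopifnot(inherits(clip, "clip_ts"), index_base %in% c(0, 1))
  idx <- c(20, 40, 25, 43) + index_base
  cols <- c(paste0("x_", idx), paste0("y_", idx))
  if (!all(cols %in% names(clip$frames)))
    fl_stop("MissingLandmarks", "clip lacks landmark columns for indices %s",
            paste(idx, collapse = ", "))
  f <- clip$frames
  ld1 <- sqrt((f[[paste0("x_", idx[1])]] - f[[paste0("x_", idx[2])]])^2 +
              (f[[paste0("y_", idx[1])]] - f[[paste0("y_", idx[2])]])^2)
  rd1 <- sqrt((f[[paste0("x_", idx[3])]] - f[[paste0("x_", idx[4])]])^2 +
              (f[[paste0("y_", idx[3])]] - f[[paste0("y_", idx[4])]])^2)
  if (interpolate_failed && any(f$success == 0) && any(f$success != 0)) {
    ok <- f$success != 0
    t <- seq_along(ld1)
    ld1 <- stats::approx(t[ok], ld1[ok], t, rule = 2)$y
    rd1 <- stats::approx(t[ok], rd1[ok], t, rule = 2)$y
  }
  list(ld1 = ld1, rd1 = rd1, frame_rate = clip$frame_rate)
}

## Continuous wavelet transform with an analytic Morlet wavelet.
## Returns complex matrix (scales x time). Torrence & Compo normalisation.
cwt_morlet <- function(x, dt, scales, omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^(ceiling(log2(n)) + 1L)  # >= 2n: linear, not circular, convolution
  xpad <- c(x, rep(0, npad - n))
  xhat <- fft(xpad)
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  norm0 <- pi^(-1 / 4)
  for (i in seq_along(scales)) {
    s <- scales[i]
    daughter <- sqrt(2 * pi * s / dt) * norm0 *
      exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    W[i, ] <- fft(xhat * daughter, inverse = TRUE)[1:n] / npad
  }
  W
}

## Torrence-Webster smoothing: Gaussian in time (sd = scale), fractional
## boxcar over 0.6/dj in scale. Operates on a (scales x time) matrix.
smooth_tw <- function(M, dt, scales, dj) {
  n <- ncol(M)
  npad <- 2^(ceiling(log2(n)) + 1L)
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / npad  # rad/sample
  out <- M
  for (i in seq_along(scales)) {
    snorm <- scales[i] / dt
    filt <- exp(-0.5 * (snorm * omega)^2)
    row <- c(M[i, ], rep(0, npad - n))
    out[i, ] <- fft(fft(row) * filt, inverse = TRUE)[1:n] / npad
  }
  ## scale smoothing: boxcar of total width 0.6/dj voices
  width <- 0.6 / dj
  nfull <- max(1L, 2L * floor((width - 1) / 2) + 1L)  # odd count of full taps
  rem <- (width - nfull) / 2
  w <- c(rem, rep(1, nfull), rem)
  w <- w / sum(w)
  half <- (length(w) - 1L) / 2L
  ns <- length(scales)
  sm <- matrix(0, ns, n)
  if (is.complex(M)) sm <- matrix(0i, ns, n)
  for (j in seq_along(w)) {
    off <- j - 1L - half
    src <- pmin(pmax(seq_len(ns) + off, 1L), ns)  # replicate edges
    sm <- sm + w[j] * out[src, , drop = FALSE]
  }
  sm
}

#' Magnitude-squared wavelet coherence of two signals
#'
#' Continuous wavelet transform of each signal with an analytic Morlet
#' wavelet (\eqn{\omega_0 = 6}), cross-spectrum smoothed with a
#' scale-matched Gaussian in time and a boxcar over 0.6 scale-octaves, and
#' coherence formed as \eqn{|S(W_{xy}/s)|^2 / (S(|W_x|^2/s) S(|W_y|^2/s))}.
#' Values lie in \[0, 1\]: 1 means perfectly synchronised (phase-locked)
#' oscillation at that scale and time, 0 means no linear relation. The cone
#' of influence marks where edge effects are negligible.
#'
#' @param x,y numeric vectors of equal length (>= 64).
#' @param dt sampling interval in seconds (e.g. 1/30 for 30 f/s video).
#' @param dj scale resolution, voices spaced `2^dj` apart (default 1/12).
#' @param omega0 Morlet centre frequency (default 6, the standard choice
#'   balancing time and frequency localisation).
#' @return Object of class `coherence_map`: `coherence` and `phase`
#'   matrices (scales x time), `scales`, `periods` (seconds), `times`,
#'   `coi_mask` (TRUE inside the cone), and `mean_coherence` (mean over the
#'   in-cone entries).
#' @export
wavelet_coherence <- function(x, y, dt, dj = 1 / 12, omega0 = 6) {
  if (length(x) != length(y))
    fl_stop("LengthMismatch", "signals differ in length (%d vs %d)",
            length(x), length(y))
  n <- length(x)
  if (n < 64) fl_stop("TooShort", "need >= 64 samples, got %d", n)
  if (dt <= 0) fl_stop("InvalidSpec", "dt must be > 0")
  if (sd(x) == 0 || sd(y) == 0)
    fl_stop("DegenerateSignal", "constant signal has no coherence")
  s0 <- 2 * dt
  J <- floor(log2(n / 8) / dj)  # up to scale n*dt/4
  scales <- s0 * 2^(dj * (0:J))
  Wx <- cwt_morlet(x, dt, scales, omega0)
  Wy <- cwt_morlet(y, dt, scales, omega0)
  inv_s <- matrix(1 / scales, nrow = length(scales), ncol = n)
  Sx <- Re(smooth_tw(Mod(Wx)^2 * inv_s, dt, scales, dj))
  Sy <- Re(smooth_tw(Mod(Wy)^2 * inv_s, dt, scales, dj))
  Sxy <- smooth_tw(Wx * Conj(Wy) * inv_s, dt, scales, dj)
  R2 <- Mod(Sxy)^2 / (Sx * Sy)
  if (any(R2 > 1 + 1e-6))
    warning("coherence overshoot beyond tolerance: max ", max(R2))
  R2 <- pmin(pmax(R2, 0), 1)
  times <- (seq_len(n) - 1) * dt
  edge <- pmin(seq_len(n) - 0.5, n - seq_len(n) + 0.5) * dt
  coi_scale <- edge / sqrt(2)  # e-folding time of the Morlet envelope
  mask <- outer(scales, coi_scale, FUN = "<=")
  structure(list(coherence = R2, phase = Arg(Sxy), scales = scales,
                 periods = 4 * pi * scales / (omega0 + sqrt(2 + omega0^2)),
                 times = times, coi_mask = mask,
                 mean_coherence = mean(R2[mask])),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf(
    "<coherence_map> %d scales x %d frames, mean in-cone coherence %.4f\n",
    nrow(x$coherence), ncol(x$coherence), x$mean_coherence))
  invisible(x)
}

#' Mean in-cone coherence of a coherence map
#'
#' @param map a `coherence_map` from [wavelet_coherence()].
#' @return Scalar in \[0, 1\]: the arithmetic mean of the coherence over
#'   entries inside the cone of influence.
#' @export
mean_coherence <- function(map) {
  stopifnot(inherits(map, "coherence_map"))
  if (!any(map$coi_mask)) fl_stop("EmptyMask", "no in-cone entries")
  mean(map$coherence[map$coi_mask])
}

#' Per-clip symmetry (mean wavelet coherence of ld1 and rd1)
#'
#' @param clip a [clip_timeseries()].
#' @param ... passed to [distance_signals()].
#' @return Scalar mean in-cone coherence.
#' @export
clip_symmetry <- function(clip, ...) {
  ds <- distance_signals(clip, ...)
  wavelet_coherence(ds$ld1, ds$rd1, dt = 1 / ds$frame_rate)$mean_coherence
}

#' Cohort symmetry table
#'
#' @param clips list of `clip_ts` objects.
#' @param ... passed to [distance_signals()].
#' @return data.frame: `participant_id`, `condition`, `mean_coherence`,
#'   `n_frames`.
#' @export
cohort_symmetry <- function(clips, ...) {
  do.call(rbind, lapply(clips, function(cl)
    data.frame(participant_id = cl$participant_id, condition = cl$condition,
               mean_coherence = clip_symmetry(cl, ...),
               n_frames = nrow(cl$frames), stringsAsFactors = FALSE)))
}
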