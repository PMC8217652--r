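test_that("distance_signals computes 2-D Euclidean distances", {
  clip <- make_clip(5)
  # left pair: landmark 20 at (0,0), landmark 40 at (3,4) -> 5
  clip$frames$x_20 <- 0; clip$frames$y_20 <- 0
  clip$frames$x_40 <- 3; clip$frames$y_40 <- 4
  # right pair coincident -> 0
  clip$frames$x_25 <- 7; clip$frames$y_25 <- 7
  clip$frames$x_43 <- 7; clip$frames$y_43 <- 7
  ds <- distance_signals(clip)
  expect_equal(ds$ld1, rep(5, 5))
  expect_equal(ds$rd1, rep(0, 5))

  # a 1-based reading shifts all four landmark indices
  ds1 <- distance_signals(clip, index_base = 1)
  expect_false(isTRUE(all.equal(ds1$ld1, ds$ld1)))
})

test_that("failed frames are linearly interpolated in distance signals", {
  clip <- make_clip(6)
  clip$frames$x_20 <- 0; clip$frames$x_40 <- 0
  clip$frames$y_20 <- 0
  clip$frames$y_40 <- c(10, 10, 999, 999, 30, 30)  # frames 3-4 failed
  clip$frames$success <- c(1, 1, 0, 0, 1, 1)
  ds <- distance_signals(clip)
  expect_equal(ds$ld1, c(10, 10, 50 / 3, 70 / 3, 30, 30))
})

test_that("Morlet CWT matches a direct time-domain convolution oracle", {
  set.seed(5)
  n <- 128
  dt <- 1 / 30
  x <- as.numeric(stats::filter(rnorm(n), rep(1 / 4, 4), circular = TRUE))
  scales <- (2 * dt) * 2^(seq(0, 3, by = 0.5))
  W <- fearleak:::cwt_morlet(x, dt, scales)
  # oracle: W_n(s) = sum_k x_k sqrt(dt/s) pi^-1/4 e^{-i w0 eta} e^{-eta^2/2},
  # eta = (k - n) dt / s, signal zero outside its support (as zero padding).
  # Scales below ~4 dt are excluded: there the frequency-domain Gaussian is
  # truncated at Nyquist while the time-sampled wavelet aliases, so the two
  # discretisations legitimately differ.
  xc <- x - mean(x)
  for (si in c(3, 5, 7)) {
    s <- scales[si]
    for (t0 in c(32, 64, 96)) {
      eta <- ((seq_len(n)) - t0) * dt / s
      psi <- sqrt(dt / s) * pi^(-1 / 4) * exp(1i * 6 * eta - eta^2 / 2)
      expect_equal(W[si, t0], sum(xc * Conj(psi)), tolerance = 1e-6)
    }
  }
})

test_that("self-coherence is 1 and coherence is symmetric and affine-invariant", {
  set.seed(8)
  g <- generate_distance_signals(256, lag = 2, noise_weight = 0.4, seed = 8)
  x <- g$left; y <- g$right
  dt <- 1 / 30

  self <- wavelet_coherence(x, x, dt)
  expect_true(all(self$coherence[self$coi_mask] >= 0.99))

  cxy <- wavelet_coherence(x, y, dt)
  cyx <- wavelet_coherence(y, x, dt)
  expect_equal(cxy$coherence, cyx$coherence, tolerance = 1e-9)
  expect_true(all(cxy$coherence >= 0 & cxy$coherence <= 1))

  # amplitude invariance: x -> a x + b
  caff <- wavelet_coherence(-2.5 * x + 40, y, dt)
  expect_equal(caff$coherence, cxy$coherence, tolerance = 1e-8)

  expect_error(wavelet_coherence(x, y[-1], dt), class = "LengthMismatch")
  expect_error(wavelet_coherence(x[1:32], y[1:32], dt), class = "TooShort")
})

test_that("equal-frequency sinusoids show high coherence and the phase lag", {
  n <- 512
  dt <- 1 / 30
  t <- (seq_len(n) - 1) * dt
  f <- 1.5  # Hz
  x <- sin(2 * pi * f * t)
  y <- sin(2 * pi * f * t - pi / 4)  # y lags x by pi/4
  map <- wavelet_coherence(x, y, dt)
  si <- which.min(abs(map$periods - 1 / f))
  in_cone <- map$coi_mask[si, ]
  expect_gt(mean(map$coherence[si, in_cone]), 0.9)
  ph <- map$phase[si, in_cone]
  # circular mean of the relative phase at the matching scale
  mean_ph <- Arg(mean(exp(1i * ph)))
  expect_equal(mean_ph, pi / 4, tolerance = 0.05)
})

test_that("mean_coherence averages over the cone of influence only", {
  g <- generate_distance_signals(128, seed = 2)
  map <- wavelet_coherence(g$left, g$right, 1 / 30)
  expect_equal(map$mean_coherence, mean(map$coherence[map$coi_mask]))
  expect_equal(mean_coherence(map), map$mean_coherence)

  ones <- map; ones$coherence[] <- 1
  expect_equal(mean_coherence(ones), 1)
  zeros <- map; zeros$coherence[] <- 0
  expect_equal(mean_coherence(zeros), 0)
  chk <- map
  chk$coherence[] <- (row(chk$coherence) + col(chk$coherence)) %% 2
  chk$coi_mask[] <- TRUE
  expect_equal(mean_coherence(chk), 0.5, tolerance = 0.01)

  none <- map; none$coi_mask[] <- FALSE
  expect_error(mean_coherence(none), class = "EmptyMask")
})

test_that("cohort symmetry table separates the coupled and noisy groups", {
  sym <- cohort_symmetry(small_cohort())
  expect_equal(nrow(sym), 12)
  m <- tapply(sym$mean_coherence, sym$condition, mean)
  expect_gt(m[["truth"]], m[["lie"]])
  expect_true(all(sym$mean_coherence >= 0 & sym$mean_coherence <= 1))
})
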