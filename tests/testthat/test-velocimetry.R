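test_that("STI of a constant video is all zero after detrending", {
  st <- frame_stack(array(0.6, c(40, 40, 8)), cal_2um())
  pts <- cbind(row = rep(20, 30), col = 6:35)
  sti <- build_sti(st, pts)
  expect_true(all(abs(sti$intensity) < 1e-12))
  expect_equal(sti$dx_um, 2.0)
  expect_equal(sti$dt_s, 1 / 60)
})

test_that("advected pattern produces a streak of the generating slope", {
  spec <- synthetic_vessel_spec(diameter_um = 16, va_mm_s = 0.5, seed = 21,
                                jitter_sigma_px = 0, noise_sigma = 0)
  gv <- generate_vessel_video(spec, cal_2um(), n_frames = 80, size = c(96, 96))
  curve <- hemoflow:::vessel_curve(spec, 96, 96)
  sti <- build_sti(gv$stack, curve[seq(1, nrow(curve), 4), ])
  est <- estimate_axial_velocity(sti)
  expect_equal(est$va_mm_s, 0.5, tolerance = 0.05)
})

test_that("curved centreline preserves the streak slope within 5 percent", {
  spec <- synthetic_vessel_spec(shape = "arc", diameter_um = 16, va_mm_s = 0.5,
                                seed = 22, jitter_sigma_px = 0, noise_sigma = 0)
  gv <- generate_vessel_video(spec, cal_2um(), n_frames = 80,
                              size = c(96, 96))
  curve <- hemoflow:::vessel_curve(spec, 96, 96)
  sti <- build_sti(gv$stack, curve[seq(1, nrow(curve), 4), ])
  est <- estimate_axial_velocity(sti)
  expect_equal(est$va_mm_s, 0.5, tolerance = 0.05)
})

test_that("segments too short for an STI are rejected", {
  st <- frame_stack(array(0.6, c(40, 40, 4)), cal_2um())
  pts <- cbind(row = c(20, 20, 20), col = 10:12)
  expect_error(build_sti(st, pts), "degenerate segment")
})

test_that("CWT filtering reduces white-noise variance", {
  set.seed(31)
  g <- generate_sti(3, shape = c(100, 80), noise_sigma = 0, seed = 31)
  noise <- g$sti
  noise$intensity <- matrix(rnorm(100 * 80), 100, 80)
  filt <- cwt_filter_sti(noise)
  expect_lt(var(as.vector(filt$intensity)), var(as.vector(noise$intensity)))
  expect_error(cwt_filter_sti(noise, scales = numeric(0)), "non-empty")
})

test_that("CWT filtering raises the streak-band energy fraction under noise", {
  # energy fraction on the streak line in the 2D spectrum: for a pattern
  # advected at s samples/frame the spectrum concentrates on f_t = -s f_x
  streak_band_fraction <- function(M, slope) {
    X <- nrow(M); T <- ncol(M)
    F2 <- Mod(stats::fft(M))^2
    kx <- ifelse(0:(X - 1) <= X / 2, 0:(X - 1), 0:(X - 1) - X)
    on <- 0
    for (i in seq_len(X)) {
      pred <- round(-slope * kx[i] * T / X)
      for (dd in -1:1) on <- on + F2[i, ((pred + dd) %% T) + 1]
    }
    on / sum(F2)
  }
  slope <- 4; X <- 100; T <- 120
  for (seed in 41:43) {
    set.seed(seed)
    xs <- seq_len(X) - 1
    M <- vapply(seq_len(T),
                function(t) sin(2 * pi * (xs - slope * (t - 1)) / 20),
                numeric(X))
    M <- M + matrix(rnorm(X * T, 0, sd(M)), X, T)  # SNR 0 dB
    sti <- structure(list(intensity = sweep(M, 1, rowMeans(M)),
                          dx_um = 1.5, dt_s = 1 / 60, segment_id = "s",
                          masked_fraction = 0, flagged = FALSE),
                     class = "sti")
    before <- streak_band_fraction(sti$intensity, slope)
    after <- streak_band_fraction(cwt_filter_sti(sti)$intensity, slope)
    expect_gt(after, before)
  }
})

test_that("filtering leaves a noise-free streak orientation unchanged", {
  g <- generate_sti(5, shape = c(100, 120), noise_sigma = 0, seed = 33)
  raw <- estimate_axial_velocity(g$sti, filter = FALSE)
  filt <- estimate_axial_velocity(g$sti, filter = TRUE)
  expect_equal(filt$va_mm_s, raw$va_mm_s, tolerance = 0.035)
})

test_that("slope, spacing and frame time convert to the stated velocity", {
  g <- generate_sti(5, shape = c(100, 120), noise_sigma = 0, dx_um = 1.5,
                    dt_s = 1 / 60, seed = 34)
  est <- estimate_axial_velocity(g$sti)
  expect_equal(est$va_mm_s, 0.45, tolerance = 0.45 * 0.05)
  expect_gt(est$quality, 0.2)
})

test_that("an all-zero STI reports no observable flow", {
  g <- generate_sti(0, shape = c(60, 40), noise_sigma = 0, seed = 35)
  # static pattern: detrending removes everything
  expect_true(all(abs(g$sti$intensity) < 1e-9))
  est <- estimate_axial_velocity(g$sti)
  expect_equal(est$va_mm_s, 0)
  expect_equal(est$quality, 0)
})

test_that("velocity is invariant to reversing the centreline direction", {
  g <- generate_sti(4, shape = c(90, 100), noise_sigma = 0.1, seed = 36)
  fwd <- estimate_axial_velocity(g$sti)
  rev <- g$sti
  rev$intensity <- rev$intensity[nrow(rev$intensity):1, ]
  bwd <- estimate_axial_velocity(rev)
  expect_equal(bwd$va_mm_s, fwd$va_mm_s, tolerance = 1e-6)
})

test_that("doubling frame rate at half the slope leaves velocity unchanged", {
  g1 <- generate_sti(4, shape = c(100, 100), noise_sigma = 0, dt_s = 1 / 60,
                     seed = 37)
  g2 <- generate_sti(2, shape = c(100, 200), noise_sigma = 0, dt_s = 1 / 120,
                     seed = 37)
  v1 <- estimate_axial_velocity(g1$sti)$va_mm_s
  v2 <- estimate_axial_velocity(g2$sti)$va_mm_s
  expect_equal(v2, v1, tolerance = 0.02 * v1)
})

test_that("noisy velocity recovery stays within 10 percent at SNR 6 dB", {
  # compact 10-rep version; the acceptance suite runs 50 reps per velocity
  for (va in c(0.2, 1.0)) {
    slope <- va * 1000 / 1.5 / 60
    errs <- vapply(1:10, function(r) {
      sd0 <- generate_sti(slope, shape = c(100, 120),
                          noise_sigma = 0, seed = 7000 + r)$truth$signal_sd
      g <- generate_sti(slope, shape = c(100, 120),
                        noise_sigma = sd0 / 10^(6 / 20), seed = 7000 + r)
      est <- estimate_axial_velocity(g$sti)
      abs(est$va_mm_s - va) / va
    }, numeric(1))
    expect_lt(median(errs), 0.10)
  }
})

test_that("quality-flagged estimates are excluded from records", {
  segs <- tibble::tibble(
    segment_id = c("a", "b", "c"),
    diameter_um = c(10, 20, 30)
  )
  vel <- tibble::tibble(
    segment_id = c("a", "b", "c"),
    va_mm_s = c(0.5, 0.4, 0.3),
    quality = c(0.9, 0, 0.8)
  )
  rec <- suppressMessages(build_segment_records(segs, vel))
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$segment_id, c("a", "c"))
})
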