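test_that("pixel series generator is deterministic and respects degenerate limits", {
  p_static <- pixel_dynamics("static", phase_correlation_time_s = Inf,
                             fringe_amplitude = 0, baseline_offset = 1234,
                             noise_sd = 0)
  expect_equal(simulate_pixel_series(p_static, 64, 100, seed = 3),
               rep(1234, 64))

  p <- pixel_dynamics("dyn", phase_correlation_time_s = 0.05)
  a <- simulate_pixel_series(p, 512, 100, seed = 42)
  b <- simulate_pixel_series(p, 512, 100, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_pixel_series(p, 512, 100, seed = 43)))

  # expected temporal mean is the baseline offset
  means <- vapply(1:200, function(s) {
    mean(simulate_pixel_series(p, 256, 100, seed = s))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - p$baseline_offset), 4 * se)

  expect_error(simulate_pixel_series(p, 1, 100), "n_frames")
  expect_error(simulate_pixel_series(p, 64, 0), "fs")
})

test_that("ensemble periodogram half-width matches the 1/(2*pi*tau) Lorentzian width", {
  tau <- 0.05
  n <- 512; fs <- 100
  p <- pixel_dynamics("lor", phase_correlation_time_s = tau,
                      fringe_amplitude = 1, baseline_offset = 1, noise_sd = 0)
  pow <- 0
  n_rep <- 250
  for (r in seq_len(n_rep)) {
    x <- simulate_pixel_series(p, n, fs, seed = 9000 + r)
    ps <- periodogram_psd(x, fs)   # oracle role: direct DFT, ensemble-averaged
    pow <- pow + ps$power
  }
  pow <- pow / n_rep
  f <- (0:(n / 2)) * fs / n
  plateau <- mean(pow[f > 0 & f < 1])
  half_f <- approx(pow[f > 0 & f < 25], f[f > 0 & f < 25],
                   xout = plateau / 2)$y
  expect_lt(abs(half_f - 1 / (2 * pi * tau)) / (1 / (2 * pi * tau)), 0.2)
})

test_that("phantom stacks carry truth labels and reject overlapping regions", {
  empty <- phantom_layout(6, 6)
  st <- simulate_phantom_stack(empty, 16, 100, seed = 1)
  expect_true(all(st$truth_labels == "background"))
  expect_equal(dim(st$intensities), c(16, 6, 6))

  expect_error(phantom_layout(8, 8, list(
    list(rows = c(1, 5), cols = c(1, 8),
         params = pixel_dynamics(phase_correlation_time_s = 0.05)),
    list(rows = c(4, 8), cols = c(1, 8),
         params = pixel_dynamics(phase_correlation_time_s = 0.05)))),
    "overlap")
  expect_error(phantom_layout(8, 8, list(
    list(rows = c(1, 9), cols = c(1, 8),
         params = pixel_dynamics(phase_correlation_time_s = 0.05)))),
    "bounds")

  # spatial-subset reproducibility: same root seed, same pixel -> same series
  lay <- phantom_layout(4, 4)
  s1 <- simulate_phantom_stack(lay, 32, 100, seed = 5)
  s2 <- simulate_phantom_stack(lay, 32, 100, seed = 5)
  expect_identical(s1$intensities, s2$intensities)
})

test_that("two-regime phantom separates mean-frequency distributions", {
  st <- two_regime_stack(side = 34, n_frames = 512, seed = 21)
  m <- compute_dynamic_image(st, metric_config())
  fast <- m$mean_frequency_hz[m$truth_labels == "fast"]   # >= 500 px/region
  slow <- m$mean_frequency_hz[m$truth_labels == "slow"]
  expect_gte(length(fast), 500)
  expect_gt(quantile(fast, 0.25), quantile(slow, 0.75))  # disjoint IQRs
  expect_gt(median(fast), median(slow))
})

test_that("decreasing correlation time strictly increases median mean frequency", {
  taus <- c(0.15, 0.05, 0.02)
  med <- vapply(seq_along(taus), function(i) {
    lay <- phantom_layout(12, 12, list(list(
      rows = c(1, 12), cols = c(1, 12),
      params = pixel_dynamics("r", phase_correlation_time_s = taus[i]))))
    st <- simulate_phantom_stack(lay, 256, 100, seed = 100 + i)
    m <- compute_dynamic_image(st, metric_config(n_frames = 256))
    median(m$mean_frequency_hz)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("static pixels sit at the noise-only amplitude floor", {
  sdn <- 40
  lay <- phantom_layout(12, 12,
    background = pixel_dynamics("bg", phase_correlation_time_s = Inf,
                                fringe_amplitude = 0, noise_sd = sdn))
  st <- simulate_phantom_stack(lay, 256, 100, seed = 8)
  m <- compute_dynamic_image(st, metric_config(n_frames = 256))
  amps <- as.vector(m$amplitude)            # 144 pixels >= 100
  floor_expected <- sdn * c4_factor(50)     # E[sd] of Gaussian noise, window 50
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - floor_expected), 3 * se)
})

test_that("tile simulator honours its construction guarantees", {
  scene <- make_scene(200, seed = 2)
  ts1 <- simulate_tile_set(scene, c(1, 1), tile_px = 64, step_px = 32, seed = 1)
  expect_equal(ts1$tiles[[1]], scene[1:64, 1:64])

  ts <- simulate_tile_set(scene, c(2, 2), tile_px = 64, step_px = 32,
                          jitter_px = 0, noise_sd = 0, seed = 1)
  a <- ts$tiles[[1]]; b <- ts$tiles[[2]]   # horizontal neighbours
  expect_equal(a[, 33:64], b[, 1:32])      # overlap identical by construction

  # zero noise and jitter: assembly at true offsets reconstructs the scene crop
  mos <- assemble_mosaic(ts$tiles, ts$true_offsets)
  expect_equal(mos, scene[1:96, 1:96])

  expect_error(simulate_tile_set(scene, c(5, 5), tile_px = 64, step_px = 60),
               "too small")
})

test_that("stained z-stack simulator returns exact ground truth", {
  # blank stack: unimodal histogram is the documented no-cells diagnostic
  zs0 <- simulate_stained_zstack(0, image_size = 64, seed = 1)
  expect_equal(zs0$n_cells, 0L)
  expect_error(two_peak_threshold(max_intensity_projection(zs0)), "bimodal")

  zs <- simulate_stained_zstack(100, cell_area_px = 50, image_size = 400,
                                n_planes = 3, fg_level = 200, bg_level = 50,
                                noise_sd = 5, seed = 7)
  expect_equal(nrow(zs$centers), 100L)
  expect_equal(sum(zs$truth_mask), 100L * 50L)
  expect_identical(zs$stack,
                   simulate_stained_zstack(100, 50, 400, 3, 200, 50, 5,
                                           seed = 7)$stack)
  expect_error(simulate_stained_zstack(5000, cell_area_px = 50,
                                       image_size = 64, seed = 1),
               "packing")
})

test_that("calibration maps target mean frequencies onto correlation times", {
  tab <- calibrate_mean_frequency(taus = c(0.02, 0.05, 0.11), n_reps = 40,
                                  n_frames = 256, seed = 99)
  expect_true(all(diff(tab$mean_frequency_hz) < 0))  # monotone decreasing
  expect_error(tau_for_mean_frequency(80), "calibrated range")
  tau <- tau_for_mean_frequency(c(5, 10))
  expect_true(all(diff(tau) < 0))
})
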