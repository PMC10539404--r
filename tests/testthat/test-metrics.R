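test_that("temporal binning averages groups and preserves means", {
  x <- rnorm(2560)
  b <- bin_series(x, 5)
  expect_length(b, 512)
  expect_equal(b[1], mean(x[1:5]))
  expect_equal(mean(b), mean(x))                      # mean conserved exactly
  expect_equal(bin_series(rep(3.5, 100), 5), rep(3.5, 20))
  expect_warning(bin_series(rnorm(11), 5), "trailing")
  expect_error(bin_series(rnorm(10), 0), "k")

  # i.i.d. variance shrinks by the bin width
  set.seed(1)
  big <- rnorm(5e5, sd = 2)
  v <- var(bin_series(big, 5))
  expect_lt(abs(v - 4 / 5) / (4 / 5), 0.02)
})

test_that("binning yields the sqrt(k) SNR gain for white noise", {
  set.seed(2)
  n_series <- 2000
  gains <- vapply(seq_len(n_series), function(i) {
    x <- rnorm(500, mean = 100, sd = 10)
    b <- bin_series(x, 5)
    (mean(b) / sd(b)) / (mean(x) / sd(x))
  }, numeric(1))
  expect_lt(abs(mean(gains) - sqrt(5)) / sqrt(5), 0.02)
})

test_that("periodogram satisfies Parseval and localizes tones", {
  expect_equal(sum(periodogram_psd(rep(7, 64), 100)$power), 0)

  n <- 500; fs <- 100   # 10 Hz sits on an exact bin (k = 50)
  tt <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 10 * tt)                   # 10 Hz is an exact bin
  ps <- periodogram_psd(x, fs)
  expect_equal(ps$frequency[which.max(ps$power)], 10)
  expect_gt(max(ps$power) / sum(ps$power), 1 - 1e-9)

  set.seed(3)
  y <- rnorm(501)                              # odd length path
  psy <- periodogram_psd(y, fs)
  v <- mean((y - mean(y))^2)
  expect_lt(abs(sum(psy$power) - v) / v, 1e-9)
  expect_error(periodogram_psd(c(1, NA, 3), 100), "non-finite")
})

test_that("PSD moments follow the weighted-frequency definitions", {
  n <- 500; fs <- 100   # 5, 10, 15 Hz are exact bins
  tt <- (0:(n - 1)) / fs
  tone <- sin(2 * pi * 10 * tt)
  ps <- periodogram_psd(tone, fs)
  bin <- fs / n
  expect_lt(abs(psd_mean_frequency(ps$frequency, ps$power) - 10), bin)
  expect_lt(psd_frequency_std(ps$frequency, ps$power), bin)

  two <- sin(2 * pi * 5 * tt) + sin(2 * pi * 15 * tt)   # equal-power tones
  ps2 <- periodogram_psd(two, fs)
  # brute-force weighted moments as oracle
  keep <- ps2$frequency > 0
  oracle_mean <- sum(ps2$frequency[keep] * ps2$power[keep]) / sum(ps2$power[keep])
  expect_equal(psd_mean_frequency(ps2$frequency, ps2$power), oracle_mean)
  expect_equal(oracle_mean, 10, tolerance = 1e-6)
  expect_equal(psd_frequency_std(ps2$frequency, ps2$power), 5, tolerance = 1e-3)

  # amplitude-scale invariance
  expect_equal(psd_mean_frequency(ps2$frequency, 17.3 * ps2$power), oracle_mean)
  expect_equal(psd_frequency_std(ps2$frequency, 0.01 * ps2$power),
               psd_frequency_std(ps2$frequency, ps2$power))

  expect_true(is.na(psd_mean_frequency(c(0, 1, 2), c(0, 0, 0))))
  expect_true(is.na(psd_frequency_std(c(0, 1, 2), c(0, 0, 0))))
})

test_that("frequency-shift translation increases mean frequency monotonically", {
  n <- 512; fs <- 100
  tt <- (0:(n - 1)) / fs
  mf <- vapply(c(5, 8, 11, 14), function(f0) {
    ps <- periodogram_psd(sin(2 * pi * f0 * tt), fs)
    psd_mean_frequency(ps$frequency, ps$power)
  }, numeric(1))
  expect_true(all(diff(mf) > 0))
})

test_that("running standard deviation matches direct-window and Monte-Carlo oracles", {
  expect_equal(running_std_mean(rep(2, 100), 50), 0)
  set.seed(4)
  x <- rnorm(300, 1000, 7)
  expect_equal(running_std_mean(x, 50), naive_running_std_mean(x, 50),
               tolerance = 1e-10)
  expect_equal(running_std_mean(x + 5e4, 50), running_std_mean(x, 50),
               tolerance = 1e-9)                 # translation invariance
  expect_error(running_std_mean(x, 1), "window")
  expect_error(running_std_mean(x, 301), "length")

  # E[running std] = sigma * c4(window) for i.i.d. Gaussian noise
  sigma <- 3; w <- 50
  vals <- vapply(seq_len(1e4), function(i) {
    running_std_mean(rnorm(60, 0, sigma), w)
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - sigma * c4_factor(w)), 2 * se)
})

test_that("image computation equals the explicit per-pixel scalar loop", {
  st <- two_regime_stack(side = 16, n_frames = 128, seed = 31)
  cfg <- metric_config(n_frames = 128)
  m <- compute_dynamic_image(st, cfg)
  for (i in c(1, 7, 16)) for (j in c(2, 9, 16)) {
    x <- st$intensities[, i, j]
    ps <- periodogram_psd(x, cfg$fs_hz)
    expect_identical(m$mean_frequency_hz[i, j],
                     psd_mean_frequency(ps$frequency, ps$power))
    expect_identical(m$frequency_std_hz[i, j],
                     psd_frequency_std(ps$frequency, ps$power))
    expect_identical(m$amplitude[i, j], running_std_mean(x, cfg$running_window))
  }
  # metric bounds hold everywhere
  expect_true(all(m$mean_frequency_hz > 0 & m$mean_frequency_hz <= 50))
  expect_true(all(m$frequency_std_hz >= 0))
  expect_true(all(m$amplitude >= 0))
})

test_that("500 Hz stacks are binned to the effective 100 Hz series", {
  p <- pixel_dynamics("r", phase_correlation_time_s = 0.05)
  cube <- array(0, dim = c(2560, 2, 2))
  for (i in 1:2) for (j in 1:2) {
    cube[, i, j] <- simulate_pixel_series(p, 2560, 500,
                                          seed = 10 * i + j)
  }
  st500 <- interf_stack(cube, frame_rate_hz = 500)
  cfg <- metric_config(n_frames = 512, fs_hz = 100, bin_width = 5)
  m <- compute_dynamic_image(st500, cfg)
  # equivalent to explicitly binning first
  x <- bin_series(cube[, 1, 1], 5)
  ps <- periodogram_psd(x[1:512], 100)
  expect_identical(m$mean_frequency_hz[1, 1],
                   psd_mean_frequency(ps$frequency, ps$power))
  # incompatible rate errors out
  st73 <- interf_stack(cube[1:73, , , drop = FALSE], frame_rate_hz = 73)
  expect_error(compute_dynamic_image(st73, cfg), "incompatible")
})

test_that("constant stacks are flagged no-signal with zero amplitude", {
  cube <- array(500, dim = c(64, 3, 3))
  st <- interf_stack(cube, 100)
  m <- compute_dynamic_image(st, metric_config(n_frames = 64))
  expect_true(all(is.na(m$mean_frequency_hz)))
  expect_true(all(m$amplitude == 0))
})
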