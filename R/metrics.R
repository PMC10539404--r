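#' Metric computation configuration
#'
#' Parameters of the per-pixel dynamic-contrast computation. The standard
#' operating point is a 512-frame series at 100 Hz; when acquiring at 500 Hz the
#' raw 2560-frame series is first binned in groups of 5 consecutive frames to an
#' effective 100 Hz series of 512 frames. Hue in the rendered image spans 3-13 Hz
#' mean frequency.
#'
#' @param n_frames Frames used per pixel series (after any binning).
#' @param fs_hz Effective sampling rate in Hz.
#' @param bin_width Temporal bin width applied when the stack rate is
#'   `bin_width` times `fs_hz` (5 for 500 Hz acquisitions, 1 for none).
#' @param running_window Sliding-window length for the amplitude metric.
#' @param hue_min_hz,hue_max_hz Mean-frequency range mapped onto the hue axis.
#' @param brightness_percentiles Lower/upper percentiles (in \[0, 100\]) of the
#'   amplitude plane used to normalize brightness.
#' @param saturation_scale Divisor rule for the frequency-spread-to-saturation
#'   map; `"quarter_fs"` uses `fs_hz / 4`.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(n_frames = 512, fs_hz = 100, bin_width = 1,
                          running_window = 50,
                          hue_min_hz = 3, hue_max_hz = 13,
                          brightness_percentiles = c(1, 99.9),
                          saturation_scale = "quarter_fs") {
  if (running_window >= n_frames) {
    stop("`running_window` must be smaller than `n_frames`", call. = FALSE)
  }
  if (!(hue_min_hz < hue_max_hz && hue_max_hz <= fs_hz / 2)) {
    stop("need hue_min_hz < hue_max_hz <= fs_hz / 2", call. = FALSE)
  }
  if (bin_width < 1) stop("`bin_width` must be >= 1", call. = FALSE)
  stopifnot(length(brightness_percentiles) == 2L,
            all(brightness_percentiles >= 0), all(brightness_percentiles <= 100))
  structure(list(n_frames = as.integer(n_frames), fs_hz = fs_hz,
                 bin_width = as.integer(bin_width),
                 running_window = as.integer(running_window),
                 hue_min_hz = hue_min_hz, hue_max_hz = hue_max_hz,
                 brightness_percentiles = brightness_percentiles,
                 saturation_scale = saturation_scale),
            class = "metric_config")
}

#' Temporal binning of an intensity series
#'
#' Averages groups of `k` consecutive samples, turning a series sampled at `fs`
#' into one at `fs / k`. For white noise this raises the SNR by sqrt(k). A
#' trailing remainder that does not fill a bin is dropped with a warning.
#'
#' @param series Numeric vector of intensity samples.
#' @param k Bin width (integer >= 1).
#' @return Numeric vector of `floor(length(series) / k)` bin means.
#' @examples
#' length(bin_series(rnorm(2560), 5))  # 512
#' @export
bin_series <- function(series, k) {
  if (length(k) != 1L || k < 1) stop("`k` must be an integer >= 1", call. = FALSE)
  k <- as.integer(k)
  if (k == 1L) return(series)
  n <- length(series)
  m <- n %/% k
  if (m * k < n) {
    warning(sprintf("dropping %d trailing sample(s) not filling a bin", n - m * k))
  }
  colMeans(matrix(series[seq_len(m * k)], nrow = k))
}

#' One-sided periodogram of a mean-removed series
#'
#' Rectangular-window periodogram of `series - mean(series)`, folded onto the
#' one-sided grid `0, fs/N, ..., fs/2`. Normalization is such that the power
#' values sum to the series' sample variance (denominator N), i.e. Parseval's
#' identity holds exactly up to floating error.
#'
#' @param series Numeric vector, length >= 2, finite.
#' @param fs Sampling rate in Hz.
#' @return A list with `frequency` (Hz, including the DC bin) and `power`.
#' @export
periodogram_psd <- function(series, fs) {
  if (!all(is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  n <- length(series)
  if (n < 2) stop("series must have at least 2 samples", call. = FALSE)
  X <- stats::fft(series - mean(series))
  p2 <- Mod(X)^2 / n^2             # two-sided, sums to var (denominator n)
  half <- n %/% 2
  k <- 0:half
  pow <- p2[k + 1]
  if (n %% 2 == 0) {
    if (half > 1) pow[2:half] <- 2 * pow[2:half]      # Nyquist bin not doubled
  } else if (half >= 1) {
    pow[2:(half + 1)] <- 2 * pow[2:(half + 1)]
  }
  list(frequency = k * fs / n, power = pow)
}

check_psd_args <- function(frequencies, power) {
  if (length(frequencies) != length(power)) {
    stop("`frequencies` and `power` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("power values must be finite and non-negative", call. = FALSE)
  }
}

#' PSD mean frequency
#'
#' Power-weighted average frequency `sum(f * P) / sum(P)` over the bins above
#' DC; the f = 0 bin is excluded because mean removal leaves it empty and its
#' inclusion would only bias the average towards zero. An all-zero spectrum has
#' no defined frequency content and yields the no-signal value `NA`, rendered
#' black downstream.
#'
#' @param frequencies Frequency grid in Hz (DC bin allowed).
#' @param power Non-negative power values on the same grid.
#' @return Mean frequency in Hz, or `NA_real_` for a no-signal spectrum.
#' @export
psd_mean_frequency <- function(frequencies, power) {
  check_psd_args(frequencies, power)
  keep <- frequencies > 0
  tot <- sum(power[keep])
  if (tot <= 0) return(NA_real_)
  sum(frequencies[keep] * power[keep]) / tot
}

#' PSD frequency standard deviation
#'
#' Power-weighted standard deviation of frequency,
#' `sqrt(sum(P * (f - fbar)^2) / sum(P))`, DC excluded as in
#' [psd_mean_frequency()]. Measures the spectral spread ("randomness") of the
#' fluctuation.
#'
#' @inheritParams psd_mean_frequency
#' @return Frequency spread in Hz, or `NA_real_` for a no-signal spectrum.
#' @export
psd_frequency_std <- function(frequencies, power) {
  check_psd_args(frequencies, power)
  keep <- frequencies > 0
  tot <- sum(power[keep])
  if (tot <= 0) return(NA_real_)
  fbar <- sum(frequencies[keep] * power[keep]) / tot
  sqrt(sum(power[keep] * (frequencies[keep] - fbar)^2) / tot)
}

#' Mean running standard deviation
#'
#' Sample standard deviation (n - 1 denominator) in every length-`window`
#' sliding window (stride 1, windows fully inside the series), averaged over all
#' windows. This is the fluctuation-amplitude metric mapped to brightness.
#'
#' @param series Numeric vector.
#' @param window Window length (2 <= window <= length(series)).
#' @return Mean running standard deviation, in camera counts.
#' @export
running_std_mean <- function(series, window) {
  n <- length(series)
  if (length(window) != 1L || window < 2) {
    stop("`window` must be an integer >= 2", call. = FALSE)
  }
  if (window > n) stop("`window` cannot exceed the series length", call. = FALSE)
  w <- as.integer(window)
  x <- series - mean(series)          # translation-invariant; improves conditioning
  c1 <- cumsum(c(0, x))
  c2 <- cumsum(c(0, x * x))
  i <- seq_len(n - w + 1L)
  s1 <- c1[i + w] - c1[i]
  s2 <- c2[i + w] - c2[i]
  v <- pmax(0, (s2 - s1 * s1 / w) / (w - 1))
  mean(sqrt(v))
}

#' Compute the three dynamic metric planes of a stack
#'
#' Applies [periodogram_psd()], [psd_mean_frequency()], [psd_frequency_std()]
#' and [running_std_mean()] to every pixel series of an interferometric stack.
#' If the stack was acquired at `bin_width` times the configured rate (e.g.
#' 2560 frames at 500 Hz with `bin_width = 5`), each series is first binned with
#' [bin_series()]; the first `n_frames` effective samples are then used. The
#' result is numerically identical to an explicit per-pixel loop over the scalar
#' operations (it is one).
#'
#' @param stack An [interf_stack()].
#' @param config A [metric_config()].
#' @return An object of class `dynamic_metrics` with matrices
#'   `mean_frequency_hz`, `frequency_std_hz`, `amplitude`, plus `config` and the
#'   `truth_labels` carried over from the stack.
#' @export
compute_dynamic_image <- function(stack, config = metric_config()) {
  stopifnot(inherits(stack, "interf_stack"), inherits(config, "metric_config"))
  fs <- stack$frame_rate_hz
  k <- 1L
  if (fs != config$fs_hz) {
    if (isTRUE(all.equal(fs, config$fs_hz * config$bin_width))) {
      k <- config$bin_width
    } else {
      stop(sprintf(paste0("stack rate %g Hz incompatible with configured %g Hz ",
                          "(bin width %d)"), fs, config$fs_hz, config$bin_width),
           call. = FALSE)
    }
  }
  d <- dim(stack$intensities)
  if (d[1] %/% k < config$n_frames) {
    stop("stack has too few frames for the configured series length", call. = FALSE)
  }
  rows <- d[2]; cols <- d[3]
  mf <- fsd <- amp <- matrix(NA_real_, rows, cols)
  for (j in seq_len(cols)) {
    for (i in seq_len(rows)) {
      x <- stack$intensities[, i, j]
      if (k > 1L) x <- suppressWarnings(bin_series(x, k))
      x <- x[seq_len(config$n_frames)]
      ps <- periodogram_psd(x, config$fs_hz)
      mf[i, j] <- psd_mean_frequency(ps$frequency, ps$power)
      fsd[i, j] <- psd_frequency_std(ps$frequency, ps$power)
      amp[i, j] <- running_std_mean(x, config$running_window)
    }
  }
  ok <- !is.na(mf)
  stopifnot(all(mf[ok] > 0), all(mf[ok] <= config$fs_hz / 2),
            all(fsd[ok] >= 0), all(amp >= 0))
  structure(list(mean_frequency_hz = mf, frequency_std_hz = fsd,
                 amplitude = amp, config = config,
                 truth_labels = stack$truth_labels),
            class = "dynamic_metrics")
}

#' @export
print.dynamic_metrics <- function(x, ...) {
  d <- dim(x$amplitude)
  cat("Dynamic metrics: ", d[1], " x ", d[2], " px (", x$config$n_frames,
      " frames @ ", x$config$fs_hz, " Hz)\n", sep = "")
  mf <- x$mean_frequency_hz
  cat(sprintf("  mean frequency: median %.2f Hz (IQR %.2f-%.2f), %d no-signal px\n",
              stats::median(mf, na.rm = TRUE),
              stats::quantile(mf, 0.25, na.rm = TRUE),
              stats::quantile(mf, 0.75, na.rm = TRUE), sum(is.na(mf))))
  cat(sprintf("  amplitude: median %.1f counts\n",
              stats::median(x$amplitude)))
  invisible(x)
}

#' @export
summary.dynamic_metrics <- function(object, ...) {
  planes <- object[c("mean_frequency_hz", "frequency_std_hz", "amplitude")]
  t(vapply(planes, function(p) {
    c(min = min(p, na.rm = TRUE),
      median = stats::median(p, na.rm = TRUE),
      max = max(p, na.rm = TRUE), na = sum(is.na(p)))
  }, numeric(4)))
}
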