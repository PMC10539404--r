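#' Calibrate mean frequency against phase correlation time
#'
#' The spectral mean frequency of the phase-diffusion fringe model has no
#' convenient closed form on a finite, sampled record, so the mapping from phase
#' correlation time tau to the recovered mean frequency is established once by
#' simulation: for each tau on a log-spaced grid, noise-free fringe series are
#' generated and the ensemble-averaged PSD mean frequency recorded. The shipped
#' package fixture (`extdata/mean_frequency_calibration.csv`) was produced by
#' this function at the standard operating point (512 frames at 100 Hz).
#'
#' @param taus Grid of correlation times in seconds.
#' @param n_frames,fs Record length and sampling rate for the calibration.
#' @param n_reps Realizations averaged per grid point.
#' @param seed Integer seed.
#' @return A data frame with columns `tau_s` and `mean_frequency_hz`, with the
#'   calibration conditions attached as attributes.
#' @seealso [tau_for_mean_frequency()]
#' @export
calibrate_mean_frequency <- function(taus = exp(seq(log(0.004), log(0.8),
                                                    length.out = 25)),
                                     n_frames = 512, fs = 100,
                                     n_reps = 200, seed = 20230928) {
  mf <- vapply(seq_along(taus), function(i) {
    p <- pixel_dynamics("cal", phase_correlation_time_s = taus[i],
                        fringe_amplitude = 1, baseline_offset = 1, noise_sd = 0)
    vals <- vapply(seq_len(n_reps), function(r) {
      x <- simulate_pixel_series(p, n_frames, fs,
                                 seed = pixel_seed(seed, i * 100000 + r))
      ps <- periodogram_psd(x, fs)
      psd_mean_frequency(ps$frequency, ps$power)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  structure(data.frame(tau_s = taus, mean_frequency_hz = mf),
            n_frames = n_frames, fs = fs, n_reps = n_reps, seed = seed)
}

calibration_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "mean_frequency_calibration.csv",
                          package = "dffoct", mustWork = TRUE)
      cache <<- utils::read.csv(path)
    }
    cache
  }
})

#' Phase correlation time for a target mean frequency
#'
#' Inverts the simulated calibration curve (mean frequency is monotone
#' decreasing in tau) by interpolating log(tau) against mean frequency.
#'
#' @param mean_freq_hz Target spectral mean frequency in Hz; must lie inside the
#'   calibrated range (about 1.5-23 Hz at 512 frames / 100 Hz).
#' @param calibration Optional calibration table from
#'   [calibrate_mean_frequency()]; defaults to the shipped fixture.
#' @return Correlation time tau in seconds.
#' @examples
#' tau_for_mean_frequency(6.75)
#' @export
tau_for_mean_frequency <- function(mean_freq_hz, calibration = NULL) {
  tab <- if (is.null(calibration)) calibration_table() else calibration
  rng <- range(tab$mean_frequency_hz)
  if (any(mean_freq_hz < rng[1] | mean_freq_hz > rng[2])) {
    stop(sprintf("target mean frequency outside the calibrated range [%.2f, %.2f] Hz",
                 rng[1], rng[2]), call. = FALSE)
  }
  o <- order(tab$mean_frequency_hz)
  exp(stats::approx(tab$mean_frequency_hz[o], log(tab$tau_s[o]),
                    xout = mean_freq_hz)$y)
}
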