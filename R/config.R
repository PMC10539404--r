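#' Camera configuration
#'
#' Describes the acquisition camera. Defaults match a 2-megapixel interferometric
#' CMOS camera run near full-well capacity: 1440 x 1440 pixels of 10 um pitch,
#' operated at 95% of the full-well capacity so that shot noise dominates, with a
#' nominal single-frame SNR of 1071 (metadata only; the simulators use an explicit
#' Gaussian noise level in counts).
#'
#' @param frame_rate_hz Acquisition rate in frames per second (100 or 500 in the
#'   standard operating points).
#' @param exposure_s Exposure time in seconds; must not exceed the frame period.
#' @param sensor_pixels Integer pair, sensor size in pixels (rows, cols).
#' @param pixel_pitch_um Physical pixel pitch in micrometres.
#' @param fwc_fraction Fraction of the full-well capacity targeted by the
#'   exposure, in (0, 1].
#' @param snr_level Nominal single-frame signal-to-noise ratio (dimensionless,
#'   metadata).
#' @return An object of class `camera_config`.
#' @examples
#' camera_config(frame_rate_hz = 500, exposure_s = 0.0013)
#' @export
camera_config <- function(frame_rate_hz = 100,
                          exposure_s = 0.0039,
                          sensor_pixels = c(1440L, 1440L),
                          pixel_pitch_um = 10,
                          fwc_fraction = 0.95,
                          snr_level = 1071) {
  stopifnot(is.numeric(frame_rate_hz), length(frame_rate_hz) == 1L)
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be positive", call. = FALSE)
  if (exposure_s > 1 / frame_rate_hz) {
    stop("`exposure_s` cannot exceed the frame period 1/frame_rate_hz", call. = FALSE)
  }
  if (fwc_fraction <= 0 || fwc_fraction > 1) {
    stop("`fwc_fraction` must be in (0, 1]", call. = FALSE)
  }
  sensor_pixels <- as.integer(sensor_pixels)
  stopifnot(length(sensor_pixels) == 2L, all(sensor_pixels > 0L))
  structure(
    list(frame_rate_hz = frame_rate_hz, exposure_s = exposure_s,
         sensor_pixels = sensor_pixels, pixel_pitch_um = pixel_pitch_um,
         fwc_fraction = fwc_fraction, snr_level = snr_level),
    class = "camera_config"
  )
}

#' Optics configuration
#'
#' Describes the imaging optics. The on-sample pixel size is derived from the
#' imaged field and the sensor width: a 200 um field imaged onto 1440 pixels
#' gives 138.9 nm per pixel (139 nm at the printed precision). Magnification,
#' wavelength and illumination power are carried as metadata; illumination
#' geometry is not modelled.
#'
#' @param magnification Total optical magnification (dimensionless, metadata).
#' @param field_um Imaged field width in micrometres.
#' @param sensor_width_px Sensor width in pixels used to derive the sample-plane
#'   pixel size.
#' @param wavelength_nm Source central wavelength in nanometres (730 or 810).
#' @param power_mw Power applied at the sample in milliwatts (metadata).
#' @return An object of class `optics_config` with the derived field
#'   `sample_pixel_nm = field_um * 1000 / sensor_width_px`.
#' @examples
#' op <- optics_config()
#' round(op$sample_pixel_nm)  # 139 nm per pixel
#' @export
optics_config <- function(magnification = 58,
                          field_um = 200,
                          sensor_width_px = 1440L,
                          wavelength_nm = 730,
                          power_mw = 3.3) {
  stopifnot(field_um > 0, sensor_width_px > 0)
  structure(
    list(magnification = magnification, field_um = field_um,
         sensor_width_px = as.integer(sensor_width_px),
         wavelength_nm = wavelength_nm, power_mw = power_mw,
         sample_pixel_nm = field_um * 1000 / sensor_width_px),
    class = "optics_config"
  )
}

#' @export
print.camera_config <- function(x, ...) {
  cat("Camera: ", paste(x$sensor_pixels, collapse = " x "),
      " px @ ", x$pixel_pitch_um, " um pitch\n", sep = "")
  cat("  frame rate ", x$frame_rate_hz, " Hz, exposure ", x$exposure_s * 1000,
      " ms, FWC fraction ", x$fwc_fraction, ", SNR ", x$snr_level, "\n", sep = "")
  invisible(x)
}

#' @export
print.optics_config <- function(x, ...) {
  cat("Optics: x", x$magnification, ", field ", x$field_um, " um over ",
      x$sensor_width_px, " px -> ", round(x$sample_pixel_nm, 1),
      " nm/pixel, lambda ", x$wavelength_nm, " nm\n", sep = "")
  invisible(x)
}
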