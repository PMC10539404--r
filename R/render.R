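#' Render dynamic metrics as an HSB color image
#'
#' Maps the three metric planes to a hue-saturation-brightness composite:
#' hue is a linear function of mean frequency clamped to
#' `[hue_min_hz, hue_max_hz]`, with the low end rendered blue and the high end
#' red (faster activity is redder); saturation decreases with the normalized
#' frequency spread (`1 - frequency_std / (fs/4)`, clipped to \[0, 1\]), so
#' narrowband activity is vivid and broadband activity washed out; brightness is
#' the fluctuation amplitude normalized between the configured global
#' percentiles and clipped to \[0, 1\]. No-signal pixels (flagged `NA` mean
#' frequency) are black.
#'
#' @param metrics A `dynamic_metrics` object from [compute_dynamic_image()].
#' @param config A [metric_config()]; defaults to the configuration stored in
#'   `metrics`.
#' @return An object of class `hsb_render`: `rgb` (rows x cols x 3 array in
#'   \[0, 1\]), plus the hue/saturation/brightness mapping parameters applied.
#' @examples
#' \donttest{
#' lay <- phantom_layout(6, 6)
#' st <- simulate_phantom_stack(lay, 64, 100, seed = 1)
#' img <- render_hsb(compute_dynamic_image(st, metric_config(n_frames = 64)))
#' }
#' @export
render_hsb <- function(metrics, config = metrics$config) {
  stopifnot(inherits(metrics, "dynamic_metrics"))
  mf <- metrics$mean_frequency_hz
  fsd <- metrics$frequency_std_hz
  amp <- metrics$amplitude

  p <- config$brightness_percentiles / 100
  lohi <- stats::quantile(amp, p, na.rm = TRUE, names = FALSE)
  if (diff(lohi) <= 0) {
    if (all(amp == 0)) {
      lohi <- c(0, 1)     # uniformly zero amplitude: a valid all-black render
    } else {
      stop("degenerate brightness percentile range; widen `brightness_percentiles`",
           call. = FALSE)
    }
  }

  t_hue <- (pmin(pmax(mf, config$hue_min_hz), config$hue_max_hz) -
              config$hue_min_hz) / (config$hue_max_hz - config$hue_min_hz)
  hue <- (2 / 3) * (1 - t_hue)               # 2/3 = blue, 0 = red
  sat <- pmin(pmax(1 - fsd / (config$fs_hz / 4), 0), 1)
  bri <- pmin(pmax((amp - lohi[1]) / (lohi[2] - lohi[1]), 0), 1)

  nosig <- is.na(mf)
  hue[nosig] <- 0; sat[nosig] <- 0; bri[nosig] <- 0

  cols <- grDevices::hsv(as.vector(hue), as.vector(sat), as.vector(bri))
  rgbm <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(nrow(mf), ncol(mf), 3L))
  out[, , 1] <- rgbm[1, ]; out[, , 2] <- rgbm[2, ]; out[, , 3] <- rgbm[3, ]

  structure(list(rgb = out, hue = hue, saturation = sat, brightness = bri,
                 hue_range_hz = c(config$hue_min_hz, config$hue_max_hz),
                 brightness_limits = lohi,
                 saturation_scale = config$fs_hz / 4),
            class = "hsb_render")
}

#' @export
print.hsb_render <- function(x, ...) {
  d <- dim(x$rgb)
  cat("HSB render: ", d[1], " x ", d[2], " px, hue ", x$hue_range_hz[1], "-",
      x$hue_range_hz[2], " Hz, brightness limits [",
      signif(x$brightness_limits[1], 4), ", ", signif(x$brightness_limits[2], 4),
      "] counts\n", sep = "")
  invisible(x)
}

#' @describeIn render_hsb Display a `dynamic_metrics` object as its HSB render.
#' @param x A `dynamic_metrics` object.
#' @param ... Passed to [render_hsb()].
#' @export
plot.dynamic_metrics <- function(x, ...) {
  r <- render_hsb(x, ...)
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(r$rgb)[1] / dim(r$rgb)[2])
  graphics::rasterImage(r$rgb, 0, 0, 1, 1, interpolate = FALSE)
  invisible(r)
}
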