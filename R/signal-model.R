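#' Pixel fluctuation parameters
#'
#' Generative model for the intensity fluctuations of one interferometric pixel:
#' a baseline offset plus a cosine fringe whose phase performs a Brownian random
#' walk, plus additive Gaussian camera noise. The phase increments have variance
#' `2 * dt / phase_correlation_time_s`, so the fringe autocorrelation decays as
#' `exp(-lag / tau)` and the fluctuation spectrum is Lorentzian-like with
#' half-width `1 / (2 * pi * tau)`. Shorter correlation times therefore mean
#' faster, higher-mean-frequency activity.
#'
#' @param regime_label Identifier for the dynamic regime (e.g. `"rpc"`,
#'   `"background"`).
#' @param target_mean_freq_hz Intended spectral mean frequency in Hz; purely
#'   descriptive unless `phase_correlation_time_s` is `NULL`, in which case it is
#'   converted through [tau_for_mean_frequency()].
#' @param phase_correlation_time_s Phase correlation time tau in seconds
#'   (controls spectral width and hence mean frequency).
#' @param fringe_amplitude Fringe amplitude in camera counts.
#' @param baseline_offset Mean intensity in camera counts (near 95% FWC for a
#'   16-bit camera, hence the default).
#' @param noise_sd Additive Gaussian camera noise, counts.
#' @return An object of class `pixel_dynamics`.
#' @examples
#' pixel_dynamics("rpc", phase_correlation_time_s = 0.05)
#' @export
pixel_dynamics <- function(regime_label = "regime",
                           target_mean_freq_hz = NULL,
                           phase_correlation_time_s = NULL,
                           fringe_amplitude = 1000,
                           baseline_offset = 60000,
                           noise_sd = 50) {
  if (is.null(phase_correlation_time_s)) {
    if (is.null(target_mean_freq_hz)) {
      stop("give either `phase_correlation_time_s` or `target_mean_freq_hz`",
           call. = FALSE)
    }
    phase_correlation_time_s <- tau_for_mean_frequency(target_mean_freq_hz)
  }
  if (fringe_amplitude < 0 || noise_sd < 0 || baseline_offset < 0) {
    stop("amplitudes, offsets and noise levels must be non-negative", call. = FALSE)
  }
  if (fringe_amplitude > 0 && phase_correlation_time_s <= 0) {
    stop("`phase_correlation_time_s` must be positive", call. = FALSE)
  }
  structure(
    list(regime_label = regime_label,
         target_mean_freq_hz = target_mean_freq_hz,
         phase_correlation_time_s = phase_correlation_time_s,
         fringe_amplitude = fringe_amplitude,
         baseline_offset = baseline_offset,
         noise_sd = noise_sd),
    class = "pixel_dynamics"
  )
}

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so simulators do not disturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic per-pixel child seed below 2^31, so any spatial subset of a
## phantom is reproducible from (root seed, pixel index) alone.
pixel_seed <- function(seed, idx) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + idx * 7919) %% 2147483629) + 1L
}

#' Simulate one interferometric pixel time series
#'
#' Draws `n_frames` samples of
#' `baseline_offset + fringe_amplitude * cos(phi_t) + noise`, where `phi_t` is a
#' Brownian phase with correlation time `params$phase_correlation_time_s` and the
#' noise is i.i.d. Gaussian. The expected temporal mean is the baseline offset.
#' Identical seeds give bit-identical series.
#'
#' @param params A [pixel_dynamics()] object.
#' @param n_frames Number of samples (>= 2).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for reproducibility.
#' @return Numeric vector of `n_frames` intensity samples (camera counts).
#' @examples
#' x <- simulate_pixel_series(pixel_dynamics(phase_correlation_time_s = 0.05),
#'                            n_frames = 512, fs = 100, seed = 1)
#' @export
simulate_pixel_series <- function(params, n_frames, fs, seed = NULL) {
  stopifnot(inherits(params, "pixel_dynamics"))
  if (length(n_frames) != 1L || n_frames < 2) {
    stop("`n_frames` must be a single value >= 2", call. = FALSE)
  }
  if (length(fs) != 1L || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  with_seed(seed, {
    n <- as.integer(n_frames)
    x <- rep(params$baseline_offset, n)
    if (params$fringe_amplitude > 0) {
      tau <- params$phase_correlation_time_s
      dphi <- rnorm(n - 1L, 0, sqrt(2 / (fs * tau)))
      phi <- cumsum(c(runif(1, 0, 2 * pi), dphi))
      x <- x + params$fringe_amplitude * cos(phi)
    }
    if (params$noise_sd > 0) x <- x + rnorm(n, 0, params$noise_sd)
    x
  })
}

#' Lay out rectangular phantom regions
#'
#' Helper building the region map consumed by [simulate_phantom_stack()]. Each
#' region is an axis-aligned rectangle (1-based inclusive pixel bounds) with its
#' own [pixel_dynamics()]; regions must not overlap.
#'
#' @param rows,cols Phantom size in pixels.
#' @param regions List of regions, each a list with fields `rows` (length-2
#'   range), `cols` (length-2 range) and `params` (a `pixel_dynamics` object).
#' @param background [pixel_dynamics()] used outside all regions; the default is
#'   a static pixel (fringe amplitude 0) with camera noise only.
#' @return An object of class `phantom_layout`.
#' @export
phantom_layout <- function(rows, cols, regions = list(),
                           background = pixel_dynamics("background",
                                                       phase_correlation_time_s = Inf,
                                                       fringe_amplitude = 0)) {
  stopifnot(rows >= 1, cols >= 1)
  occupied <- matrix(FALSE, rows, cols)
  for (rg in regions) {
    stopifnot(inherits(rg$params, "pixel_dynamics"))
    ri <- rg$rows[1]:rg$rows[2]; ci <- rg$cols[1]:rg$cols[2]
    if (min(ri) < 1 || max(ri) > rows || min(ci) < 1 || max(ci) > cols) {
      stop("region exceeds phantom bounds", call. = FALSE)
    }
    if (any(occupied[ri, ci])) stop("phantom regions overlap", call. = FALSE)
    occupied[ri, ci] <- TRUE
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 regions = regions, background = background),
            class = "phantom_layout")
}

#' Simulate a structured dynamic phantom stack
#'
#' Builds a frames x rows x cols intensity cube in which every pixel follows the
#' [pixel_dynamics()] of the region containing it (background elsewhere), each
#' pixel with an independent, deterministically derived random stream. The
#' returned stack carries a ground-truth label map.
#'
#' @param layout A [phantom_layout()].
#' @param n_frames Frames per pixel series.
#' @param fs Sampling rate, Hz.
#' @param seed Root seed; per-pixel child seeds are derived from it.
#' @param camera,optics Optional [camera_config()] / [optics_config()] metadata.
#' @return An [interf_stack()] with `truth_labels` filled with region labels.
#' @examples
#' lay <- phantom_layout(8, 8, list(list(
#'   rows = c(1, 4), cols = c(1, 8),
#'   params = pixel_dynamics("fast", phase_correlation_time_s = 0.02))))
#' st <- simulate_phantom_stack(lay, n_frames = 64, fs = 100, seed = 7)
#' @export
simulate_phantom_stack <- function(layout, n_frames, fs, seed = 1L,
                                   camera = NULL, optics = NULL) {
  stopifnot(inherits(layout, "phantom_layout"))
  rows <- layout$rows; cols <- layout$cols
  labels <- matrix(layout$background$regime_label, rows, cols)
  par_map <- matrix(list(layout$background), rows, cols)
  for (rg in layout$regions) {
    ri <- rg$rows[1]:rg$rows[2]; ci <- rg$cols[1]:rg$cols[2]
    labels[ri, ci] <- rg$params$regime_label
    par_map[ri, ci] <- list(rg$params)
  }
  cube <- array(0, dim = c(n_frames, rows, cols))
  for (j in seq_len(cols)) {
    for (i in seq_len(rows)) {
      idx <- (j - 1L) * rows + i
      cube[, i, j] <- simulate_pixel_series(par_map[[i, j]], n_frames, fs,
                                            seed = pixel_seed(seed, idx))
    }
  }
  interf_stack(cube, frame_rate_hz = fs, camera = camera, optics = optics,
               truth_labels = labels)
}

#' Interferometric image stack container
#'
#' Wraps a frames x rows x cols cube of non-negative intensities with its
#' sampling metadata and an optional ground-truth label map.
#'
#' @param intensities 3-D numeric array, frames x rows x cols, finite and >= 0.
#' @param frame_rate_hz Sampling rate in Hz.
#' @param camera,optics Optional configuration metadata.
#' @param truth_labels Optional rows x cols matrix of regime labels.
#' @return An object of class `interf_stack`.
#' @export
interf_stack <- function(intensities, frame_rate_hz,
                         camera = NULL, optics = NULL, truth_labels = NULL) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (!all(is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be positive", call. = FALSE)
  if (!is.null(truth_labels) &&
      !identical(dim(truth_labels), dim(intensities)[2:3])) {
    stop("`truth_labels` must match the spatial shape", call. = FALSE)
  }
  structure(list(intensities = intensities, frame_rate_hz = frame_rate_hz,
                 camera = camera, optics = optics, truth_labels = truth_labels),
            class = "interf_stack")
}

#' @export
print.interf_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat("Interferometric stack: ", d[1], " frames x ", d[2], " x ", d[3],
      " px @ ", x$frame_rate_hz, " Hz\n", sep = "")
  cat("  intensity range [", round(min(x$intensities)), ", ",
      round(max(x$intensities)), "] counts",
      if (!is.null(x$truth_labels)) "; truth labels present", "\n", sep = "")
  invisible(x)
}

#' @export
dim.interf_stack <- function(x) dim(x$intensities)

#' Simulate an overlapping tile set from a scene
#'
#' Crops a grid of tiles from a reference scene at lattice positions
#' `(r - 1) * step_px`, `(c - 1) * step_px`, perturbed by a known integer jitter,
#' optionally adding Gaussian noise. With zero jitter and noise, overlapping
#' areas of neighbouring tiles agree exactly by construction.
#'
#' @param scene 2-D numeric matrix, the ground-truth scene.
#' @param grid Integer pair `(rows, cols)` of the tile grid.
#' @param tile_px Tile side length in pixels.
#' @param step_px Lattice step between neighbouring tiles (< `tile_px`).
#' @param jitter_px Maximum absolute integer jitter per axis (uniform on
#'   `-jitter_px..jitter_px`).
#' @param noise_sd Additive Gaussian noise on each tile, counts.
#' @param seed Integer seed.
#' @return A list of class `tile_set`: `tiles` (list of matrices, row-major grid
#'   order), `true_offsets` (n x 2 matrix of 0-based (y, x) crop positions),
#'   `grid`, `tile_px`, `step_px`.
#' @export
simulate_tile_set <- function(scene, grid, tile_px, step_px,
                              jitter_px = 0, noise_sd = 0, seed = NULL) {
  stopifnot(is.matrix(scene), length(grid) == 2L, all(grid >= 1))
  if (step_px >= tile_px && any(grid > 1)) {
    stop("`step_px` must be smaller than `tile_px`", call. = FALSE)
  }
  need_r <- (grid[1] - 1) * step_px + tile_px + 2 * jitter_px
  need_c <- (grid[2] - 1) * step_px + tile_px + 2 * jitter_px
  if (need_r > nrow(scene) || need_c > ncol(scene)) {
    stop("scene too small for the requested tile grid", call. = FALSE)
  }
  with_seed(seed, {
    n <- grid[1] * grid[2]
    tiles <- vector("list", n)
    offs <- matrix(0L, n, 2, dimnames = list(NULL, c("y", "x")))
    k <- 0L
    for (r in seq_len(grid[1])) {
      for (cc in seq_len(grid[2])) {
        k <- k + 1L
        jy <- if (jitter_px > 0) sample.int(2L * jitter_px + 1L, 1L) - jitter_px - 1L else 0L
        jx <- if (jitter_px > 0) sample.int(2L * jitter_px + 1L, 1L) - jitter_px - 1L else 0L
        y0 <- (r - 1L) * step_px + jitter_px + jy   # 0-based crop origin
        x0 <- (cc - 1L) * step_px + jitter_px + jx
        tl <- scene[y0 + seq_len(tile_px), x0 + seq_len(tile_px)]
        if (noise_sd > 0) tl <- tl + rnorm(length(tl), 0, noise_sd)
        tiles[[k]] <- tl
        offs[k, ] <- c(y0, x0)
      }
    }
    structure(list(tiles = tiles, true_offsets = offs, grid = as.integer(grid),
                   tile_px = as.integer(tile_px), step_px = as.integer(step_px)),
              class = "tile_set")
  })
}

## Pixel offsets (relative to a centre) of a disk-shaped region of exactly
## `area_px` pixels: pixels sorted by distance from the centre, ties broken
## deterministically.
disk_offsets <- function(area_px) {
  r <- ceiling(sqrt(area_px / pi)) + 2L
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d <- g$dy^2 + g$dx^2
  o <- order(d, g$dy, g$dx)
  g[o[seq_len(area_px)], , drop = FALSE]
}

#' Simulate a stained-nuclei z-stack with known ground truth
#'
#' Places `n_cells` non-overlapping disks of exactly `cell_area_px` pixels each
#' at the foreground level, distributed across `n_planes` planes of a background-
#' level stack, then adds Gaussian noise. Disk centres are kept far enough apart
#' that no two disks touch, even diagonally, so connected-component counts equal
#' the true cell number. The maximum-intensity projection of the result has a
#' bimodal histogram (background vs foreground).
#'
#' @param n_cells Number of disks to place.
#' @param cell_area_px Disk area in pixels (e.g. 50 at x20, 200 at x40).
#' @param image_size Side length of each square plane, pixels.
#' @param n_planes Number of z planes.
#' @param fg_level,bg_level Foreground / background intensity, counts.
#' @param noise_sd Additive Gaussian noise per plane, counts.
#' @param seed Integer seed.
#' @param max_tries Placement attempts before giving up with a packing error.
#' @return A list of class `stained_zstack`: `stack` (planes x rows x cols
#'   array), `n_cells`, `centers` (n x 2 matrix), `cell_area_px`, `truth_mask`
#'   (logical matrix of all disk pixels).
#' @export
simulate_stained_zstack <- function(n_cells, cell_area_px = 50, image_size = 256,
                                    n_planes = 3, fg_level = 200, bg_level = 50,
                                    noise_sd = 5, seed = NULL,
                                    max_tries = 200 * max(1, n_cells)) {
  stopifnot(n_cells >= 0, cell_area_px >= 1, image_size >= 8, n_planes >= 1)
  with_seed(seed, {
    offs <- disk_offsets(cell_area_px)
    rad <- ceiling(sqrt(cell_area_px / pi))
    margin <- rad + 2L
    min_sep2 <- (2 * rad + 3)^2   # >= 2 px gap between disks
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place the requested disks without overlap (packing error)",
             call. = FALSE)
      }
      cy <- sample(seq(margin, image_size - margin), 1L)
      cx <- sample(seq(margin, image_size - margin), 1L)
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2 >= min_sep2)) {
        centers <- rbind(centers, c(cy, cx))
      }
    }
    stack <- array(bg_level, dim = c(n_planes, image_size, image_size))
    truth <- matrix(FALSE, image_size, image_size)
    if (n_cells > 0) {
      plane_of <- rep_len(seq_len(n_planes), n_cells)
      for (k in seq_len(n_cells)) {
        ii <- centers[k, 1] + offs$dy
        jj <- centers[k, 2] + offs$dx
        stack[cbind(plane_of[k], ii, jj)] <- fg_level
        truth[cbind(ii, jj)] <- TRUE
      }
    }
    if (noise_sd > 0) {
      stack <- stack + array(rnorm(length(stack), 0, noise_sd), dim = dim(stack))
    }
    structure(list(stack = stack, n_cells = as.integer(n_cells),
                   centers = centers, cell_area_px = as.integer(cell_area_px),
                   truth_mask = truth),
              class = "stained_zstack")
  })
}
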