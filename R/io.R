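#' Write / read an interferometric stack as raw binary + JSON sidecar
#'
#' The cube is quantized to little-endian unsigned 16-bit counts (values
#' rounded and clipped to the camera full-well count) in frame-major order; the
#' sidecar records shape, dtype, byte order and sampling metadata so the file
#' is self-describing.
#'
#' @param stack An [interf_stack()].
#' @param path Output path for the binary file; the sidecar is `path` +
#'   `".json"`.
#' @param full_well Saturation count for clipping (default 65535).
#' @return `path`, invisibly.
#' @export
write_stack_raw <- function(stack, path, full_well = 65535) {
  stopifnot(inherits(stack, "interf_stack"))
  d <- dim(stack$intensities)
  x <- pmin(pmax(round(stack$intensities), 0), full_well)
  con <- file(path, "wb"); on.exit(close(con))
  # writeBin size=2 needs values representable as signed 16-bit on the wire;
  # recentre to signed then undo on read.
  writeBin(as.integer(x) - 32768L, con, size = 2L, endian = "little")
  meta <- list(shape = d, dtype = "uint16", byte_order = "little",
               order = "frame_major_column_major",
               frame_rate_hz = stack$frame_rate_hz,
               recentred_by = 32768L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack_raw
#' @return For `read_stack_raw`, the reconstructed [interf_stack()].
#' @export
read_stack_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  con <- file(path, "rb"); on.exit(close(con))
  x <- readBin(con, "integer", n = prod(d), size = 2L, signed = TRUE,
               endian = meta$byte_order) + meta$recentred_by
  interf_stack(array(as.numeric(x), dim = d), frame_rate_hz = meta$frame_rate_hz)
}

#' Write / read an interferometric stack as multi-page 16-bit TIFF
#'
#' One TIFF page per frame, 16-bit, with the sampling metadata in a JSON
#' sidecar (`path` + `".json"`).
#'
#' @inheritParams write_stack_raw
#' @param path Output TIFF path.
#' @return `path` invisibly; for `read_stack_tiff`, an [interf_stack()].
#' @export
write_stack_tiff <- function(stack, path, full_well = 65535) {
  stopifnot(inherits(stack, "interf_stack"))
  d <- dim(stack$intensities)
  pages <- lapply(seq_len(d[1]), function(f) {
    pmin(pmax(round(stack$intensities[f, , ]), 0), full_well) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(frame_rate_hz = stack$frame_rate_hz, dtype = "uint16"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  cube <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) cube[f, , ] <- round(pages[[f]] * 65535)
  interf_stack(cube, frame_rate_hz = meta$frame_rate_hz)
}

#' Write / read dynamic metric planes as a 3-page float TIFF
#'
#' Plane order: mean frequency, frequency spread, amplitude. TIFF float storage
#' is limited to \[0, 1\], so each plane is written divided by a scale factor
#' (fs/2 for the frequency planes, the amplitude maximum for the amplitude
#' plane) recorded in the JSON sidecar together with the metric configuration.
#' No-signal pixels are stored as the scale sentinel value 1 plus flagged
#' indices in the sidecar.
#'
#' @param metrics A `dynamic_metrics` object.
#' @param path Output TIFF path.
#' @return `path` invisibly; for `read_metrics_tiff`, a `dynamic_metrics`
#'   object (without truth labels).
#' @export
write_metrics_tiff <- function(metrics, path) {
  stopifnot(inherits(metrics, "dynamic_metrics"))
  cfg <- metrics$config
  fscale <- cfg$fs_hz / 2
  amax <- max(metrics$amplitude, 1e-12)
  nosig <- which(is.na(metrics$mean_frequency_hz))
  mf <- metrics$mean_frequency_hz / fscale; mf[nosig] <- 1
  fsd <- metrics$frequency_std_hz / fscale; fsd[nosig] <- 1
  planes <- list(mf, fsd, metrics$amplitude / amax)
  planes <- lapply(planes, function(p) pmin(pmax(p, 0), 1))
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(plane_order = c("mean_frequency_hz", "frequency_std_hz", "amplitude"),
         scales = c(fscale, fscale, amax),
         no_signal_indices = nosig,
         config = unclass(cfg)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_tiff
#' @export
read_metrics_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  cfg <- do.call(metric_config, meta$config[setdiff(names(meta$config), NULL)])
  mf <- pages[[1]] * meta$scales[1]
  fsd <- pages[[2]] * meta$scales[2]
  amp <- pages[[3]] * meta$scales[3]
  if (length(meta$no_signal_indices)) {
    mf[meta$no_signal_indices] <- NA_real_
    fsd[meta$no_signal_indices] <- NA_real_
  }
  structure(list(mean_frequency_hz = mf, frequency_std_hz = fsd,
                 amplitude = amp, config = cfg, truth_labels = NULL),
            class = "dynamic_metrics")
}

#' Write an HSB render as an 8-bit PNG
#'
#' @param render An `hsb_render` object.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_render_png <- function(render, path) {
  stopifnot(inherits(render, "hsb_render"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the `png` package is required to write PNG renders", call. = FALSE)
  }
  png::writePNG(render$rgb, path)
  invisible(path)
}

#' Write / read tile positions as CSV
#'
#' Columns: `tile_id`, `grid_row`, `grid_col`, `x_px`, `y_px` — 0-based pixel
#' positions of tile top-left corners, x rightward, y downward.
#'
#' @param positions n x 2 matrix of (y, x) positions (0-based) in row-major
#'   grid order, or a `tile_offsets` object.
#' @param grid Integer pair (rows, cols) of the tile grid.
#' @param path Output CSV path.
#' @return `path` invisibly; for `read_tile_positions`, a data frame.
#' @export
write_tile_positions <- function(positions, grid, path) {
  if (inherits(positions, "tile_offsets")) positions <- positions$positions
  n <- nrow(positions)
  stopifnot(n == grid[1] * grid[2])
  df <- data.frame(tile_id = seq_len(n) - 1L,
                   grid_row = rep(seq_len(grid[1]) - 1L, each = grid[2]),
                   grid_col = rep(seq_len(grid[2]) - 1L, times = grid[1]),
                   x_px = positions[, 2], y_px = positions[, 1])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_positions
#' @export
read_tile_positions <- function(path) {
  utils::read.csv(path)
}

#' Read timing parameters from a TOML, YAML or JSON file
#'
#' Timing files use flat `key = value` TOML (a minimal subset: optional
#' `[section]` headers, numeric/boolean/string scalars, `#` comments); `.yaml`
#' and `.json` files are read with the corresponding parsers. Recognized keys
#' (top level or under `[timing]`) are the arguments of
#' [acquisition_timing()], plus `frame_rate_hz` as an alternative to
#' `frame_period_s`.
#'
#' @param path Path to the parameter file.
#' @return An [acquisition_timing()].
#' @export
read_timing_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    "yaml" = ,
    "yml" = {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the `yaml` package is required for YAML timing files", call. = FALSE)
      }
      yaml::read_yaml(path)
    },
    parse_toml_subset(path))
  if (!is.null(vals$timing)) vals <- vals$timing
  if (!is.null(vals$frame_rate_hz) && is.null(vals$frame_period_s)) {
    vals$frame_period_s <- 1 / vals$frame_rate_hz
  }
  vals <- vals[intersect(names(vals), names(formals(acquisition_timing)))]
  do.call(acquisition_timing, vals)
}

## Minimal flat TOML reader: [section] headers, scalar key = value lines
## (numbers, booleans, quoted strings), full-line or trailing # comments.
parse_toml_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); section <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse TOML line: ", ln, call. = FALSE)
    key <- kv[2]; raw <- trimws(kv[3])
    val <- if (grepl('^".*"$', raw)) {
      gsub('^"|"$', "", raw)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      as.numeric(raw)
    }
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

#' Write ground truth alongside simulated data
#'
#' Writes the ground truth of a simulator result — tile offsets, cell centres
#' and counts, or phantom labels — as CSV plus a JSON summary, so simulated
#' fixtures are self-describing on disk.
#'
#' @param truth A `tile_set`, `stained_zstack`, or `interf_stack` with truth
#'   labels.
#' @param stem Output path stem; files `stem.csv` and `stem.json` are written.
#' @return The paths written, invisibly.
#' @export
write_ground_truth <- function(truth, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  if (inherits(truth, "tile_set")) {
    utils::write.csv(data.frame(tile_id = seq_len(nrow(truth$true_offsets)) - 1L,
                                y_px = truth$true_offsets[, 1],
                                x_px = truth$true_offsets[, 2]),
                     csv, row.names = FALSE)
    jsonlite::write_json(list(kind = "tile_set", grid = truth$grid,
                              tile_px = truth$tile_px, step_px = truth$step_px),
                         js, auto_unbox = TRUE)
  } else if (inherits(truth, "stained_zstack")) {
    utils::write.csv(data.frame(cell_id = seq_len(truth$n_cells) - 1L,
                                row_px = truth$centers[, 1],
                                col_px = truth$centers[, 2]),
                     csv, row.names = FALSE)
    jsonlite::write_json(list(kind = "stained_zstack", n_cells = truth$n_cells,
                              cell_area_px = truth$cell_area_px),
                         js, auto_unbox = TRUE)
  } else if (inherits(truth, "interf_stack") && !is.null(truth$truth_labels)) {
    lab <- truth$truth_labels
    df <- data.frame(row_px = as.vector(row(lab)), col_px = as.vector(col(lab)),
                     label = as.vector(lab))
    utils::write.csv(df, csv, row.names = FALSE)
    jsonlite::write_json(list(kind = "phantom_labels",
                              labels = sort(unique(as.vector(lab)))),
                         js, auto_unbox = TRUE)
  } else {
    stop("no ground truth available for this object", call. = FALSE)
  }
  invisible(c(csv, js))
}
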