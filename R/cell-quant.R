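#' Magnification configuration for area-based counting
#'
#' Pairs a pixel size with the fixed mean surface-per-cell factor used by the
#' area-based count: 50 pixels at x20 (0.56 um pixels, an equivalent circle of
#' radius 2.23 um) and 200 pixels at x40 (0.26 um pixels, radius 2.07 um). The
#' factors describe a cell's 2-D area at its equatorial plane.
#'
#' @param name `"x20"` or `"x40"` for the standard presets, or any label when
#'   both numeric fields are supplied.
#' @param pixel_size_um Pixel size in micrometres.
#' @param cell_area_px Mean surface per cell, pixels.
#' @param min_region_size Connected components must be strictly larger than
#'   this to be retained.
#' @return An object of class `magnification_config`.
#' @examples
#' magnification_config("x20")
#' @export
magnification_config <- function(name = c("x20", "x40"),
                                 pixel_size_um = NULL, cell_area_px = NULL,
                                 min_region_size = 25) {
  if (is.null(pixel_size_um) || is.null(cell_area_px)) {
    name <- match.arg(name)
    pixel_size_um <- c(x20 = 0.56, x40 = 0.26)[[name]]
    cell_area_px <- c(x20 = 50, x40 = 200)[[name]]
  }
  stopifnot(pixel_size_um > 0, cell_area_px >= 1, min_region_size >= 0)
  structure(list(name = name[1], pixel_size_um = pixel_size_um,
                 cell_area_px = cell_area_px,
                 min_region_size = min_region_size),
            class = "magnification_config")
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a planes x rows x cols stack (or a `stained_zstack`) to a 2-D image
#' by the per-pixel maximum across planes.
#'
#' @param zstack 3-D numeric array (planes first) or a
#'   [simulate_stained_zstack()] result.
#' @return Numeric matrix, rows x cols.
#' @export
max_intensity_projection <- function(zstack) {
  if (inherits(zstack, "stained_zstack")) zstack <- zstack$stack
  if (!is.array(zstack) || length(dim(zstack)) != 3L || dim(zstack)[1] < 1L) {
    stop("`zstack` must be a planes x rows x cols array with >= 1 plane",
         call. = FALSE)
  }
  out <- zstack[1, , ]
  for (p in seq_len(dim(zstack)[1])[-1]) out <- pmax(out, zstack[p, , ])
  out
}

## Moving-average smoothing with edge shrinkage (window clipped at the ends).
smooth_counts <- function(counts, width = 5L) {
  n <- length(counts)
  half <- width %/% 2L
  vapply(seq_len(n), function(i) {
    mean(counts[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Two-peak histogram threshold
#'
#' Implements the bimodal-histogram binarization rule: the 256-bin intensity
#' histogram is smoothed with a fixed 5-bin moving average, the two dominant
#' peaks are identified (one for the background noise, one for the meaningful
#' signal), and the threshold is set at the intensity between them that
#' minimizes the overlap of the two modes — computed as the intersection of two
#' Gaussian components fitted to either side of the inter-peak valley, which is
#' also the point minimizing the total misclassified mass. If the intersection
#' search fails the deepest valley between the peaks is used. Pixels at or
#' above the threshold are foreground.
#'
#' @param image Numeric matrix (typically a [max_intensity_projection()]).
#' @param n_bins Number of histogram bins.
#' @param smooth_width Moving-average width, bins.
#' @param min_peak_sep Minimum separation between the two peaks, bins.
#' @return The threshold intensity, with attributes `peaks` (the two peak
#'   intensities), `valley`, and `components` (fitted weight/mean/sd per mode).
#' @export
two_peak_threshold <- function(image, n_bins = 256L, smooth_width = 5L,
                               min_peak_sep = 10L) {
  v <- as.vector(image)
  if (!all(is.finite(v))) stop("image contains non-finite values", call. = FALSE)
  rng <- range(v)
  if (diff(rng) == 0) {
    stop("flat image: histogram is degenerate, no bimodality", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- hist(v, breaks = breaks, plot = FALSE)
  raw <- h$counts
  cnt <- smooth_counts(raw, smooth_width)
  mids <- h$mids
  n <- length(cnt)
  is_peak <- c(FALSE, cnt[2:(n - 1)] > cnt[1:(n - 2)] &
                 cnt[2:(n - 1)] >= cnt[3:n], FALSE)
  is_peak[1] <- cnt[1] > cnt[2]
  is_peak[n] <- cnt[n] > cnt[n - 1]
  peaks <- which(is_peak)
  if (length(peaks) < 2L) {
    stop("histogram is not bimodal: fewer than two peaks detected", call. = FALSE)
  }
  peaks <- peaks[order(cnt[peaks], decreasing = TRUE)]
  p1 <- peaks[1]
  # A second mode is accepted only when a wide, deep valley separates it from
  # the dominant peak (>= 10 consecutive bins below a quarter of the smaller
  # peak) and it carries non-negligible mass; this rejects noise-tail bumps of
  # unimodal histograms while keeping faint but isolated signal modes.
  p2 <- NA_integer_
  for (cand in peaks[-1]) {
    if (abs(cand - p1) < min_peak_sep) next
    between <- cnt[(min(p1, cand) + 1L):(max(p1, cand) - 1L)]
    deep <- between <= 0.25 * min(cnt[p1], cnt[cand])
    runs <- rle(deep)
    run_len <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    mass <- sum(raw[max(1L, cand - 5L):min(n, cand + 5L)])
    if (run_len >= 10L && mass >= 20) { p2 <- cand; break }
  }
  if (is.na(p2)) {
    stop("histogram is not bimodal: no second mode separated by a deep valley",
         call. = FALSE)
  }
  lo <- min(p1, p2); hi <- max(p1, p2)
  valley <- lo + which.min(cnt[lo:hi]) - 1L
  split_val <- mids[valley]

  fit_mode <- function(sel) {
    w <- mean(sel)
    list(weight = w, mean = mean(v[sel]), sd = stats::sd(v[sel]))
  }
  c1 <- fit_mode(v < split_val)
  c2 <- fit_mode(v >= split_val)
  thr <- mids[valley]
  if (is.finite(c1$sd) && is.finite(c2$sd) && c1$sd > 0 && c2$sd > 0) {
    ld <- function(x) {
      stats::dnorm(x, c1$mean, c1$sd, log = TRUE) + log(c1$weight) -
        stats::dnorm(x, c2$mean, c2$sd, log = TRUE) - log(c2$weight)
    }
    root <- tryCatch(
      stats::uniroot(ld, lower = c1$mean, upper = c2$mean, tol = 1e-10)$root,
      error = function(e) NULL)
    if (!is.null(root)) thr <- root
  }
  structure(thr,
            peaks = sort(c(mids[p1], mids[p2])), valley = mids[valley],
            components = list(low = c1, high = c2))
}

## 8-connectivity connected-component labeling by frontier BFS (vectorized
## frontier expansion). Returns an integer matrix of labels, 0 = background.
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  isfg <- as.vector(mask)
  seen <- logical(nr * nc)
  nb_off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  cur <- 0L
  for (s in fg) {
    if (seen[s]) next
    cur <- cur + 1L
    frontier <- s; seen[s] <- TRUE
    while (length(frontier)) {
      lab[frontier] <- cur
      row_f <- ((frontier - 1L) %% nr) + 1L
      cand <- rep(frontier, each = 8L) + nb_off
      rowc <- rep(row_f, each = 8L) + rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L),
                                          length(frontier))
      keep <- cand >= 1L & cand <= nr * nc & rowc >= 1L & rowc <= nr
      cand <- unique(cand[keep])
      cand <- cand[isfg[cand] & !seen[cand]]
      seen[cand] <- TRUE
      frontier <- cand
    }
  }
  lab
}

#' Binarize an image and filter small regions
#'
#' Sets pixels at or above the threshold to one, labels connected components
#' with 8-connectivity, and retains only regions strictly larger than
#' `min_region_size` pixels (guards against over-segmentation and miscounting).
#'
#' @param image Numeric matrix.
#' @param threshold Intensity threshold (foreground is `>= threshold`).
#' @param min_region_size Strict lower bound on retained component area.
#' @return A list: `mask` (logical matrix of retained pixels), `region_sizes`
#'   (integer vector of retained component areas), `n_removed` (components
#'   dropped by the size filter).
#' @export
binarize_and_filter <- function(image, threshold, min_region_size = 25) {
  stopifnot(is.matrix(image), length(threshold) == 1L, is.finite(threshold))
  raw <- image >= threshold
  lab <- label_components_8(raw)
  if (max(lab) == 0L) {
    return(list(mask = raw & FALSE, region_sizes = integer(0), n_removed = 0L))
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes > min_region_size)
  mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  list(mask = mask, region_sizes = as.integer(sizes[keep]),
       n_removed = length(sizes) - length(keep))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Area-based cell count from a mask
#'
#' Estimates the number of cells as the total retained mask area divided by the
#' fixed mean surface-per-cell factor, rounded to the nearest integer
#' (half away from zero).
#'
#' @param mask Logical matrix from [binarize_and_filter()], or that function's
#'   result list.
#' @param config A [magnification_config()].
#' @return Integer cell count (>= 0).
#' @examples
#' m <- matrix(FALSE, 30, 30); m[1:20, 1:25] <- TRUE   # 500 px
#' estimate_count(m, magnification_config("x20"))       # 10
#' @export
estimate_count <- function(mask, config) {
  stopifnot(inherits(config, "magnification_config"))
  if (is.list(mask)) mask <- mask$mask
  as.integer(round_half_away(sum(mask) / config$cell_area_px))
}

#' Colocalization count of two channels
#'
#' Combines two binarized channel masks with a pixel-wise logical AND, then
#' applies the size discrimination and area-based count of the single-channel
#' pipeline to the intersection.
#'
#' @param mask_a,mask_b Logical matrices of the same shape (binarized channels).
#' @param config A [magnification_config()].
#' @return Integer count of colocalized cells.
#' @export
colocalization_count <- function(mask_a, mask_b, config) {
  stopifnot(is.matrix(mask_a), is.matrix(mask_b))
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("channel masks must have the same shape", call. = FALSE)
  }
  both <- binarize_and_filter(1 * (mask_a & mask_b), threshold = 1,
                              min_region_size = config$min_region_size)
  estimate_count(both$mask, config)
}

#' Marker-positive pixel fraction relative to a reference channel
#'
#' Ratio of marker-positive to reference-positive pixel counts (e.g. a stain
#' versus the DAPI nuclear reference). At the pixel level the per-cell surface
#' factor cancels, so only threshold-positive pixels matter.
#'
#' @param mask_marker,mask_reference Logical matrices of the same shape.
#' @return The fraction (in \[0, 1\] whenever the marker is a subset of the
#'   reference).
#' @export
pixel_ratio_vs_reference <- function(mask_marker, mask_reference) {
  if (!identical(dim(mask_marker), dim(mask_reference))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  nref <- sum(mask_reference)
  if (nref == 0) stop("reference mask is empty: ratio undefined", call. = FALSE)
  sum(mask_marker) / nref
}

#' Equivalent circle radius of a per-cell area factor
#'
#' Radius in micrometres of a circle whose pixel area equals `area_px`:
#' `pixel_size_um * sqrt(area_px / pi)`. The standard factors give 2.23 um
#' (50 px at 0.56 um) and 2.07 um (200 px at 0.26 um).
#'
#' @param area_px Area in pixels (> 0).
#' @param pixel_size_um Pixel size in micrometres.
#' @return Radius in micrometres.
#' @examples
#' round(equivalent_circle_radius(50, 0.56), 2)   # 2.23
#' round(equivalent_circle_radius(200, 0.26), 2)  # 2.07
#' @export
equivalent_circle_radius <- function(area_px, pixel_size_um) {
  if (any(area_px <= 0)) stop("`area_px` must be positive", call. = FALSE)
  pixel_size_um * sqrt(area_px / pi)
}

#' Full cell-counting pipeline on a z-stack
#'
#' Runs the five-step pipeline: maximum-intensity projection, two-peak
#' histogram thresholding, binarization, size discrimination (regions strictly
#' larger than `config$min_region_size`), and area-based counting.
#'
#' @param zstack 3-D array (planes x rows x cols) or a
#'   [simulate_stained_zstack()] result.
#' @param config A [magnification_config()].
#' @param ... Passed to [two_peak_threshold()].
#' @return An object of class `segmentation_result`: `mask`, `threshold`,
#'   `region_sizes`, `estimated_count`, `config`.
#' @examples
#' \donttest{
#' zs <- simulate_stained_zstack(10, cell_area_px = 50, image_size = 128, seed = 1)
#' count_cells(zs, magnification_config("x20"))$estimated_count   # 10
#' }
#' @export
count_cells <- function(zstack, config = magnification_config("x20"), ...) {
  mip <- max_intensity_projection(zstack)
  thr <- two_peak_threshold(mip, ...)
  bf <- binarize_and_filter(mip, as.numeric(thr), config$min_region_size)
  structure(list(mask = bf$mask, threshold = as.numeric(thr),
                 threshold_detail = attributes(thr),
                 region_sizes = bf$region_sizes,
                 estimated_count = estimate_count(bf$mask, config),
                 config = config),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Segmentation: threshold ", signif(x$threshold, 5), ", ",
      length(x$region_sizes), " region(s), total area ", sum(x$region_sizes),
      " px\n", sep = "")
  cat("  estimated count: ", x$estimated_count, " (", x$config$name,
      ", ", x$config$cell_area_px, " px/cell)\n", sep = "")
  invisible(x)
}
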