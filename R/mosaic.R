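#' Plan a regular mosaic tile grid
#'
#' Lays `grid_rows x grid_cols` square tiles on a regular lattice with step
#' `step_px` between neighbouring tile origins. The canvas along each axis is
#' `tile_px + (n - 1) * step_px`. With 1440-px tiles, a step of 744 px
#' reproduces the 2928-px canvas of a 3 x 3 mosaic; a step of 720 px is an exact
#' 50% overlap.
#'
#' @param grid_rows,grid_cols Number of tile rows / columns (>= 1).
#' @param tile_px Tile side length in pixels.
#' @param step_px Lattice step in pixels, 0 < step_px <= tile_px (larger steps
#'   would leave gaps).
#' @return An object of class `mosaic_plan`: `positions` (n x 2 matrix of
#'   0-based (y, x) tile origins in row-major order), `canvas_px` (rows, cols),
#'   and the input geometry.
#' @examples
#' plan_grid(3, 3, tile_px = 1440, step_px = 744)$canvas_px  # 2928 2928
#' @export
plan_grid <- function(grid_rows, grid_cols, tile_px = 1440, step_px = 744) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, tile_px >= 1)
  if (step_px <= 0 || step_px > tile_px) {
    stop("`step_px` must satisfy 0 < step_px <= tile_px (no gaps)", call. = FALSE)
  }
  pos <- as.matrix(expand.grid(
    x = (seq_len(grid_cols) - 1L) * step_px,
    y = (seq_len(grid_rows) - 1L) * step_px))[, c("y", "x"), drop = FALSE]
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 tile_px = as.integer(tile_px), step_px = as.integer(step_px),
                 positions = pos,
                 canvas_px = c(tile_px + (grid_rows - 1L) * step_px,
                               tile_px + (grid_cols - 1L) * step_px)),
            class = "mosaic_plan")
}

#' @export
print.mosaic_plan <- function(x, ...) {
  cat("Mosaic plan: ", x$grid_rows, " x ", x$grid_cols, " tiles of ",
      x$tile_px, " px, step ", x$step_px, " px -> canvas ",
      x$canvas_px[1], " x ", x$canvas_px[2], " px\n", sep = "")
  invisible(x)
}

## Normalized cross-correlation of the overlap of `a` and `b` when b's origin
## sits at integer shift (dy, dx) relative to a's. Returns NA when the overlap
## is too small or has zero variance.
overlap_ncc <- function(a, b, dy, dx, min_overlap = 16L) {
  ar <- nrow(a); ac <- ncol(a); br <- nrow(b); bc <- ncol(b)
  y1 <- max(1L, 1L + dy); y2 <- min(ar, br + dy)
  x1 <- max(1L, 1L + dx); x2 <- min(ac, bc + dx)
  if (y2 - y1 + 1L < min_overlap || x2 - x1 + 1L < min_overlap) return(NA_real_)
  va <- as.vector(a[y1:y2, x1:x2])
  vb <- as.vector(b[(y1:y2) - dy, (x1:x2) - dx])
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Register a pair of overlapping tiles
#'
#' Exhaustively searches integer shifts within `search_radius` of the nominal
#' shift and returns the one maximizing the normalized cross-correlation of the
#' overlap region; the correlation value is the confidence. Registration is
#' translation-only (stage-scanned acquisition; no rotation or scale, no
#' subpixel refinement). If every candidate overlap is too small or has zero
#' variance the nominal shift is retained with a failure flag.
#'
#' @param tile_a,tile_b Numeric matrices of the same shape.
#' @param nominal_shift Integer pair `(dy, dx)`: position of `tile_b`'s origin
#'   relative to `tile_a`'s.
#' @param search_radius Maximum deviation from the nominal shift, pixels.
#' @param min_overlap Minimum overlap extent (pixels) in each dimension.
#' @return A list: `shift` (the refined `(dy, dx)`), `confidence` (peak NCC, or
#'   `NA` on failure), `ok` (logical).
#' @export
register_pair <- function(tile_a, tile_b, nominal_shift, search_radius = 5,
                          min_overlap = 16L) {
  stopifnot(is.matrix(tile_a), is.matrix(tile_b), length(nominal_shift) == 2L)
  nominal_shift <- as.integer(round(nominal_shift))
  r <- as.integer(search_radius)
  if (is.na(overlap_ncc(tile_a, tile_b, nominal_shift[1], nominal_shift[2],
                        min_overlap))) {
    # check geometry only: flat overlaps still pass here via variance test below
    ya <- nrow(tile_a); xa <- ncol(tile_a)
    oy <- min(ya, nrow(tile_b) + nominal_shift[1]) - max(1L, 1L + nominal_shift[1]) + 1L
    ox <- min(xa, ncol(tile_b) + nominal_shift[2]) - max(1L, 1L + nominal_shift[2]) + 1L
    if (oy < min_overlap || ox < min_overlap) {
      stop("overlap at the nominal shift is smaller than `min_overlap`",
           call. = FALSE)
    }
  }
  best <- c(NA_integer_, NA_integer_); best_c <- -Inf
  for (dy in (nominal_shift[1] - r):(nominal_shift[1] + r)) {
    for (dx in (nominal_shift[2] - r):(nominal_shift[2] + r)) {
      v <- overlap_ncc(tile_a, tile_b, dy, dx, min_overlap)
      if (!is.na(v) && v > best_c) { best_c <- v; best <- c(dy, dx) }
    }
  }
  if (!is.finite(best_c)) {
    return(list(shift = nominal_shift, confidence = NA_real_, ok = FALSE))
  }
  list(shift = as.integer(best), confidence = best_c, ok = TRUE)
}

#' Resolve global tile positions from pairwise registrations
#'
#' Registers every horizontally and vertically adjacent tile pair of a planned
#' grid, then resolves global positions by chaining measured shifts from the
#' top-left anchor tile along a maximum-confidence spanning tree (simple and
#' deterministic; adequate for lattice grids). Pairs whose registration failed
#' fall back to the nominal lattice shift with confidence below every
#' successful pair.
#'
#' @param tiles List of tile matrices in row-major grid order.
#' @param plan A [mosaic_plan()] whose grid matches `length(tiles)`.
#' @param search_radius Passed to [register_pair()].
#' @return An object of class `tile_offsets`: `positions` (n x 2, 0-based
#'   (y, x), anchor at the origin), `pairs` (data frame of pairwise
#'   measurements: from, to, dy, dx, confidence, ok).
#' @export
resolve_tile_positions <- function(tiles, plan, search_radius = 5) {
  stopifnot(inherits(plan, "mosaic_plan"),
            length(tiles) == plan$grid_rows * plan$grid_cols)
  gr <- plan$grid_rows; gc <- plan$grid_cols
  id <- function(r, cc) (r - 1L) * gc + cc
  pairs <- NULL
  for (r in seq_len(gr)) {
    for (cc in seq_len(gc)) {
      a <- id(r, cc)
      for (nb in list(c(r, cc + 1L), c(r + 1L, cc))) {
        if (nb[1] > gr || nb[2] > gc) next
        b <- id(nb[1], nb[2])
        nom <- plan$positions[b, ] - plan$positions[a, ]
        reg <- register_pair(tiles[[a]], tiles[[b]], nom, search_radius)
        pairs <- rbind(pairs, data.frame(
          from = a, to = b, dy = reg$shift[1], dx = reg$shift[2],
          confidence = if (reg$ok) reg$confidence else -Inf, ok = reg$ok))
      }
    }
  }
  n <- length(tiles)
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("y", "x")))
  pos[1, ] <- c(0, 0)
  placed <- rep(FALSE, n); placed[1] <- TRUE
  # Prim-style growth: always attach the highest-confidence edge on the frontier
  while (!all(placed)) {
    cand <- pairs[xor(placed[pairs$from], placed[pairs$to]), , drop = FALSE]
    if (nrow(cand) == 0) stop("tile graph is disconnected", call. = FALSE)
    e <- cand[which.max(cand$confidence), ]
    if (placed[e$from]) {
      pos[e$to, ] <- pos[e$from, ] + c(e$dy, e$dx); placed[e$to] <- TRUE
    } else {
      pos[e$from, ] <- pos[e$to, ] - c(e$dy, e$dx); placed[e$from] <- TRUE
    }
  }
  structure(list(positions = pos, pairs = pairs), class = "tile_offsets")
}

#' Assemble tiles into a blended mosaic
#'
#' Places every tile at its resolved position and combines overlapping pixels by
#' linear-ramp feathering: each tile pixel carries a weight proportional to its
#' distance from the nearest tile edge, and contributions are normalized so that
#' weights sum to one wherever at least one tile covers the canvas. Where all
#' contributing tiles agree, any such convex combination returns the common
#' value, so noise-free consistent tiles reproduce the scene exactly. The canvas
#' is the bounding box of the placed tiles.
#'
#' @param tiles List of equally sized tile matrices.
#' @param offsets An n x 2 matrix of (y, x) tile origins (0-based), or a
#'   `tile_offsets` object from [resolve_tile_positions()].
#' @param blend `"feather"` (default) or `"average"` (uniform weights).
#' @return The mosaic as a numeric matrix; pixels covered by no tile are `NA`.
#' @export
assemble_mosaic <- function(tiles, offsets, blend = c("feather", "average")) {
  blend <- match.arg(blend)
  if (length(tiles) == 0) stop("empty tile list", call. = FALSE)
  if (inherits(offsets, "tile_offsets")) offsets <- offsets$positions
  offsets <- round(offsets)
  stopifnot(is.matrix(offsets), nrow(offsets) == length(tiles))
  th <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  for (tl in tiles) stopifnot(nrow(tl) == th, ncol(tl) == tw)
  offsets[, 1] <- offsets[, 1] - min(offsets[, 1])
  offsets[, 2] <- offsets[, 2] - min(offsets[, 2])
  H <- max(offsets[, 1]) + th; W <- max(offsets[, 2]) + tw
  wy <- pmin(seq_len(th), th + 1L - seq_len(th))   # distance from nearest edge
  wx <- pmin(seq_len(tw), tw + 1L - seq_len(tw))
  wtile <- if (blend == "feather") outer(wy, wx, pmin) else matrix(1, th, tw)
  acc <- matrix(0, H, W); wsum <- matrix(0, H, W)
  for (k in seq_along(tiles)) {
    ri <- offsets[k, 1] + seq_len(th)
    ci <- offsets[k, 2] + seq_len(tw)
    acc[ri, ci] <- acc[ri, ci] + tiles[[k]] * wtile
    wsum[ri, ci] <- wsum[ri, ci] + wtile
  }
  out <- acc / wsum
  out[wsum == 0] <- NA_real_
  out
}
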