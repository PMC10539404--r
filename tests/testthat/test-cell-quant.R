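test_that("maximum-intensity projection equals the naive loop oracle", {
  set.seed(1)
  cube <- array(rnorm(4 * 32 * 32), dim = c(4, 32, 32))
  expect_equal(max_intensity_projection(cube), naive_mip(cube))
  one <- array(rnorm(1 * 8 * 8), dim = c(1, 8, 8))
  expect_equal(max_intensity_projection(one), one[1, , ])

  # each plane holds one distinct bright pixel; all appear in the projection
  cube2 <- array(0, dim = c(3, 10, 10))
  cube2[cbind(1:3, c(2, 5, 8), c(3, 6, 9))] <- 100
  mip <- max_intensity_projection(cube2)
  expect_equal(sum(mip == 100), 3)
  expect_error(max_intensity_projection(array(0, c(0, 4, 4))), "plane")
})

test_that("two-peak threshold lands at the Gaussian component intersection", {
  set.seed(2)
  # equal weights, equal variances: intersection at the midpoint 125
  v <- c(rnorm(40000, 50, 10), rnorm(40000, 200, 10))
  img <- matrix(v, 200, 400)
  thr <- two_peak_threshold(img)
  bin_w <- diff(range(img)) / 256
  expect_lt(abs(as.numeric(thr) - 125), bin_w)
  pk <- attr(thr, "peaks")
  expect_true(pk[1] < as.numeric(thr) && as.numeric(thr) < pk[2])

  # unequal variances: compare with the exhaustive misclassified-mass scan
  v2 <- c(rnorm(60000, 60, 6), rnorm(20000, 180, 25))
  img2 <- matrix(v2, 200, 400)
  thr2 <- as.numeric(two_peak_threshold(img2))
  w1 <- 0.75; w2 <- 0.25
  grid <- seq(60, 180, length.out = 4097)
  miscl <- w1 * pnorm(grid, 60, 6, lower.tail = FALSE) + w2 * pnorm(grid, 180, 25)
  oracle <- grid[which.min(miscl)]
  expect_lt(abs(thr2 - oracle), diff(range(img2)) / 256 * 2)

  expect_error(two_peak_threshold(matrix(7, 10, 10)), "flat")
  set.seed(3)
  expect_error(two_peak_threshold(matrix(rnorm(10000), 100, 100)), "bimodal")
})

test_that("size discrimination is strict and 8-connected", {
  img <- matrix(0, 60, 60)
  img[2:6, 2:6] <- 1                 # 25 px -> removed (strict >)
  img[20:32, 10:11] <- 1             # 26 px -> retained
  img[40:47, 40:44] <- 1             # 40 px -> retained
  bf <- binarize_and_filter(img, threshold = 1, min_region_size = 25)
  expect_equal(sort(bf$region_sizes), c(26L, 40L))
  expect_equal(sum(bf$mask), sum(bf$region_sizes))   # bookkeeping identity
  expect_equal(bf$n_removed, 1L)

  # diagonal chains are one component under 8-connectivity
  dg <- matrix(0, 40, 40)
  idx <- 1:30
  dg[cbind(idx, idx)] <- 1
  bfd <- binarize_and_filter(dg, 1, min_region_size = 25)
  expect_equal(bfd$region_sizes, 30L)

  # labeling agrees with the naive scalar BFS oracle
  set.seed(4)
  rnd <- matrix(runif(900) > 0.6, 30, 30)
  lab <- dffoct:::label_components_8(rnd)
  oracle <- naive_label8(rnd)
  expect_equal(max(lab), max(oracle))
  # identical partition: co-membership matrices agree on a sample
  pick <- sample(which(rnd), 40)
  expect_equal(outer(lab[pick], lab[pick], "=="),
               outer(oracle[pick], oracle[pick], "=="))

  empty <- binarize_and_filter(matrix(0, 10, 10), threshold = 1)
  expect_equal(sum(empty$mask), 0)
  expect_length(empty$region_sizes, 0)
})

test_that("area-based counts follow the fixed surface-per-cell factors", {
  m500 <- matrix(FALSE, 40, 40); m500[1:20, 1:25] <- TRUE
  expect_equal(estimate_count(m500, magnification_config("x20")), 10L)
  m1000 <- matrix(FALSE, 40, 40); m1000[1:25, 1:40] <- TRUE
  expect_equal(estimate_count(m1000, magnification_config("x40")), 5L)
  expect_equal(estimate_count(matrix(FALSE, 5, 5),
                              magnification_config("x20")), 0L)
})

test_that("colocalization applies AND then size filter then counting", {
  cfg <- magnification_config("x20")
  a <- matrix(FALSE, 50, 50); b <- matrix(FALSE, 50, 50)
  a[1:10, 1:10] <- TRUE; b[30:40, 30:40] <- TRUE
  expect_equal(colocalization_count(a, b, cfg), 0L)       # disjoint
  expect_equal(colocalization_count(a, a, cfg),
               estimate_count(binarize_and_filter(1 * a, 1, 25)$mask, cfg))
  # engineered 100-px overlap -> 2 cells at factor 50
  a2 <- matrix(FALSE, 50, 50); b2 <- matrix(FALSE, 50, 50)
  a2[1:20, 1:10] <- TRUE; b2[11:30, 1:10] <- TRUE         # overlap 10 x 10
  expect_equal(colocalization_count(a2, b2, cfg), 2L)
  expect_error(colocalization_count(a, matrix(FALSE, 10, 10), cfg), "shape")
})

test_that("pixel ratios against a reference channel are plain count ratios", {
  ref <- matrix(FALSE, 40, 40); ref[1:25, 1:40] <- TRUE    # 1000 px
  mk <- matrix(FALSE, 40, 40); mk[1:25, 1:10] <- TRUE      # 250 px, subset
  expect_equal(pixel_ratio_vs_reference(mk, ref), 0.25)
  expect_equal(pixel_ratio_vs_reference(ref, ref), 1.0)
  expect_equal(pixel_ratio_vs_reference(mk & FALSE, ref), 0)
  r <- pixel_ratio_vs_reference(mk, ref)
  expect_true(r >= 0 && r <= 1)
  expect_error(pixel_ratio_vs_reference(mk, ref & FALSE), "empty")
})

test_that("equivalent circle radii match the magnification presets", {
  expect_equal(round(equivalent_circle_radius(50, 0.56), 2), 2.23)
  expect_equal(round(equivalent_circle_radius(200, 0.26), 2), 2.07)
  expect_equal(equivalent_circle_radius(pi, 1.0), 1.0)
  expect_error(equivalent_circle_radius(0, 1), "positive")
})

test_that("the full pipeline recovers exact counts and is monotone in disks", {
  cfg <- magnification_config("x20")
  for (n in c(1, 10, 100)) {
    zs <- simulate_stained_zstack(n, cell_area_px = 50,
                                  image_size = if (n == 100) 400 else 160,
                                  n_planes = 3, fg_level = 200, bg_level = 50,
                                  noise_sd = 5, seed = n)
    res <- count_cells(zs, cfg)
    expect_equal(res$estimated_count, n)
    expect_true(all(res$region_sizes > cfg$min_region_size))
    pk <- res$threshold_detail$peaks
    expect_true(pk[1] < res$threshold && res$threshold < pk[2])
  }
  # monotonicity: adding a disk never decreases the count
  counts <- vapply(c(5, 6, 10, 20), function(n) {
    count_cells(simulate_stained_zstack(n, 50, 256, seed = 77),
                cfg)$estimated_count
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})
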