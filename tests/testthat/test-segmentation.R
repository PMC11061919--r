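two_class_volume <- function() {
  # 500 voxels at 10 and 500 at 90 in a 10x10x10 grid, bright phase connected
  a <- array(10, c(10, 10, 10))
  a[, , 6:10] <- 90
  image_volume(a, 0.05)
}

test_that("Otsu threshold separates a two-level volume exactly", {
  vol <- two_class_volume()
  thr <- otsu_threshold(vol, n_bins = 256)
  expect_gt(thr, 10)
  expect_lt(thr, 90)
  expect_identical(sum(vol$data > thr), 500L)
})

test_that("Otsu threshold equals an exhaustive between-class variance scan", {
  set.seed(3)
  vals <- c(rnorm(400, 30, 8), rnorm(200, 85, 6))
  vol <- image_volume(array(vals, c(10, 10, 6)), 0.05)
  n_bins <- 64
  thr <- otsu_threshold(vol, n_bins = n_bins)
  # oracle: scan every interior bin edge, scoring classes from raw values
  edges <- seq(min(vals), max(vals), length.out = n_bins + 1)
  score <- function(e) {
    lo <- vals[vals <= e]; hi <- vals[vals > e]
    if (!length(lo) || !length(hi)) return(-Inf)
    (length(lo) / length(vals)) * (length(hi) / length(vals)) *
      (mean(lo) - mean(hi))^2
  }
  scores <- sapply(edges[2:n_bins], score)
  best <- edges[1 + which.max(scores)]
  expect_equal(thr, best)
})

test_that("Otsu rejects constant volumes and lands between bimodal modes", {
  flat <- image_volume(array(7, c(4, 4, 4)), 0.05)
  expect_error(otsu_threshold(flat), "constant")

  set.seed(1)
  vals <- c(rnorm(5e4, 20, 5), rnorm(5e4, 80, 5))
  vol <- image_volume(array(vals, c(100, 100, 10)), 0.05)
  thr <- otsu_threshold(vol)
  expect_gt(thr, 35)
  expect_lt(thr, 65)
})

test_that("homogeneity scores regions against the VOI dispersion", {
  set.seed(2)
  vals <- rep(c(10, 90), 50)
  vol <- image_volume(array(vals, c(10, 10, 1)), 0.05)
  const_region <- array(FALSE, dim(vol$data)); const_region[c(1, 3, 5)] <- TRUE
  expect_equal(homogeneity(vol, const_region), 1)  # constant intensities
  all_region <- array(TRUE, dim(vol$data))
  expect_equal(homogeneity(vol, all_region), 0)    # sd(region) = sd(VOI)
  two <- array(FALSE, dim(vol$data)); two[1:2] <- TRUE  # one 10, one 90
  expect_equal(homogeneity(vol, two), 0)           # clipped at 0
  expect_error(homogeneity(vol, array(FALSE, dim(vol$data))), "empty")
})

test_that("region growing recovers a connected intensity class exactly", {
  vol <- two_class_volume()
  seg <- grow_regions(vol, t = 0.5)
  expect_identical(seg$bone, vol$data == 90)
  expect_identical(seg$bone | (vol$data == 10), array(TRUE, dim(vol$data)))
})

test_that("at a vanishing threshold the grown bone region is its seed set", {
  set.seed(9)
  a <- array(sample(seq_len(8000)), c(20, 20, 20))  # all-distinct intensities
  vol <- image_volume(a, 0.05)
  cfg <- arg_config()
  seg <- grow_regions(vol, t = 1e-9, config = cfg)
  seeds <- vol$data >= quantile(vol$data, 1 - cfg$seed_quantile_bone)
  expect_identical(seg$bone_grown, seeds)
  # the final nearest-mean assignment still partitions the whole VOI
  expect_true(all(xor(seg$bone, !seg$bone)))
  expect_true(all(seg$bone[seeds]))
})

test_that("region growing is deterministic and monotone in the threshold", {
  ph <- small_plate_phantom(extent = 1)
  noise <- local({ set.seed(31); rnorm(length(ph$volume$data), 0, 40) })
  vol <- image_volume(ph$volume$data + array(noise, dim(ph$volume$data)),
                      ph$volume$spacing_mm)
  s1 <- grow_regions(vol, t = 0.3)
  s2 <- grow_regions(vol, t = 0.3)
  expect_identical(s1$bone, s2$bone)
  expect_identical(s1$homogeneity_trace, s2$homogeneity_trace)
  # grown bone regions are nested along the schedule (before final assignment)
  prev <- NULL
  for (t in c(0.05, 0.15, 0.4, 1.0)) {
    g <- grow_regions(vol, t = t)$bone_grown
    if (!is.null(prev)) expect_true(all(g[prev]), info = paste("t =", t))
    prev <- g
  }
})

test_that("ARG selects the jointly most homogeneous partition over the schedule", {
  ph <- small_plate_phantom(extent = 1.5)
  seg <- arg_segment(ph$volume)
  expect_equal(dice(seg$bone, ph$truth_mask$data), 1)
  tr <- seg$homogeneity_trace
  expect_identical(nrow(tr), length(arg_config()$threshold_schedule))
  expect_true(seg$chosen_threshold %in% tr$threshold)
  expect_equal(tr$combined[tr$threshold == seg$chosen_threshold][1],
               max(tr$combined))
  # first maximum wins on ties
  expect_equal(seg$chosen_threshold,
               tr$threshold[which.max(tr$combined)])
})

test_that("ARG and Otsu agree voxel-for-voxel on separable volumes", {
  ph <- small_plate_phantom(extent = 1.5)
  sa <- arg_segment(ph$volume)
  so <- otsu_segment(ph$volume)
  expect_identical(sa$bone, so$bone)
})

test_that("ARG output is binary, confined to the VOI, and partitions it", {
  ph <- small_plate_phantom(extent = 1.5)
  m <- array(FALSE, dim(ph$volume$data))
  m[3:28, 3:28, 3:28] <- TRUE
  voi <- mask_volume(m, ph$volume$spacing_mm)
  seg <- arg_segment(ph$volume, voi)
  expect_true(all(!seg$bone[!voi$data]))
  expect_true(is.logical(seg$bone))
  # bone and background partition the VOI
  inside <- seg$bone[voi$data]
  expect_identical(sum(inside) + sum(!inside), sum(voi$data))
})

test_that("empty seed sets and invalid configs are rejected", {
  expect_error(arg_config(threshold_schedule = c(0.5, 0.4)), "increasing")
  expect_error(arg_config(seed_quantile_bone = 0.5,
                          seed_quantile_background = 0.6), "overlap")
  expect_error(arg_config(connectivity = 18), "6 or 26")
  flat <- image_volume(array(5, c(4, 4, 4)), 0.05)
  expect_error(grow_regions(flat, t = 0.5), "constant")
  vol <- two_class_volume()
  expect_error(grow_regions(vol, t = 0), "> 0")
})
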