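#' Configuration for automated region growing
#'
#' The ARG segmentation grows a bone and a background region from intensity
#' seeds under a homogeneity threshold `t` (in multiples of the VOI intensity
#' standard deviation), sweeps `t` over a schedule, and keeps the iteration
#' where the two regions are jointly most homogeneous. The schedule starts
#' very tight (strong under-segmentation) and ends over-inclusive.
#'
#' @param threshold_schedule strictly increasing numeric vector (length >= 2)
#'   of homogeneity thresholds, unitless multiples of the VOI intensity SD.
#'   Default: 20 values geometrically spaced from 0.05 to 2.
#' @param connectivity growth neighbourhood, 6 or 26.
#' @param seed_quantile_bone fraction in (0, 1): voxels above the
#'   `1 - seed_quantile_bone` VOI intensity quantile seed the bone region
#'   (bone is the bright minority phase).
#' @param seed_quantile_background fraction in (0, 1): voxels below this
#'   intensity quantile seed the background region.
#' @param rng_seed integer, recorded for provenance (the algorithm itself is
#'   deterministic).
#' @return An object of class `arg_config`.
#' @export
arg_config <- function(threshold_schedule = exp(seq(log(0.05), log(2),
                                                    length.out = 20)),
                       connectivity = 26,
                       seed_quantile_bone = 0.02,
                       seed_quantile_background = 0.20,
                       rng_seed = 1L) {
  if (length(threshold_schedule) < 2 || any(threshold_schedule <= 0) ||
      any(diff(threshold_schedule) <= 0)) {
    stop("threshold_schedule must be strictly increasing, positive, length >= 2")
  }
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  stopifnot(seed_quantile_bone > 0, seed_quantile_bone < 1,
            seed_quantile_background > 0, seed_quantile_background < 1)
  if (seed_quantile_bone + seed_quantile_background >= 1) {
    stop("seed quantiles overlap: seed_quantile_bone + seed_quantile_background must be < 1")
  }
  structure(
    list(threshold_schedule = as.numeric(threshold_schedule),
         connectivity = as.integer(connectivity),
         seed_quantile_bone = seed_quantile_bone,
         seed_quantile_background = seed_quantile_background,
         rng_seed = as.integer(rng_seed)),
    class = "arg_config"
  )
}

#' Otsu threshold inside a volume of interest
#'
#' Histogram-based threshold maximizing the between-class intensity variance
#' over VOI voxels; the reference segmentation path for high-CNR data.
#' Candidate thresholds are the interior bin edges of an equal-width
#' histogram; ties are broken toward the lower threshold.
#'
#' @param volume an [image_volume()].
#' @param voi optional [mask_volume()]; defaults to the whole volume.
#' @param n_bins number of histogram bins.
#' @return The threshold (intensity units). Bone is `intensity > threshold`.
#' @export
otsu_threshold <- function(volume, voi = NULL, n_bins = 256L) {
  stopifnot(inherits(volume, "image_volume"))
  vals <- if (is.null(voi)) as.vector(volume$data) else {
    check_same_lattice(volume, voi)
    volume$data[voi$data]
  }
  if (length(vals) == 0L) stop("empty VOI")
  rng <- range(vals)
  if (diff(rng) == 0) stop("constant intensities inside the VOI; no threshold exists")
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(vals, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  n <- length(vals)
  w0 <- cumsum(counts) / n                  # class weight below edge k+1
  mu0 <- cumsum(counts * mids)
  mu_t <- mu0[n_bins]
  # between-class variance at each interior edge
  k <- seq_len(n_bins - 1L)
  w <- w0[k]
  valid <- w > 0 & w < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w[valid] - mu0[k][valid])^2 /
    (w[valid] * (1 - w[valid]))
  best <- which.max(sigma_b)                # which.max -> first (lowest) tie
  edges[best + 1L]
}

#' Homogeneity of a region
#'
#' `1 - sd(region) / sd(VOI)`, clipped to `[0, 1]`: 1 for a constant-intensity
#' region, 0 for a region as heterogeneous as the whole VOI. Regions with a
#' single voxel score 1 (zero dispersion).
#'
#' @param volume an [image_volume()].
#' @param region logical array of region membership (non-empty).
#' @param voi optional [mask_volume()] defining the VOI normalization;
#'   defaults to the whole volume.
#' @return Score in `[0, 1]`.
#' @export
homogeneity <- function(volume, region, voi = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  region <- as_volume_array(region)
  if (!any(region != 0)) stop("empty region")
  voi_vals <- if (is.null(voi)) as.vector(volume$data) else volume$data[voi$data]
  sd_voi <- stats::sd(voi_vals)
  if (!is.finite(sd_voi) || sd_voi == 0) stop("constant VOI; homogeneity undefined")
  reg_vals <- volume$data[region != 0]
  sd_reg <- if (length(reg_vals) < 2L) 0 else stats::sd(reg_vals)
  min(1, max(0, 1 - sd_reg / sd_voi))
}

arg_seeds <- function(vals_voi, config) {
  q_hi <- stats::quantile(vals_voi, 1 - config$seed_quantile_bone,
                          names = FALSE)
  q_lo <- stats::quantile(vals_voi, config$seed_quantile_background,
                          names = FALSE)
  if (q_lo >= q_hi) stop("seed quantiles overlap in intensity; seeds not separable")
  list(hi = q_hi, lo = q_lo)
}

new_segmentation <- function(bone, voi, spacing_mm, method,
                             chosen_threshold = NA_real_,
                             homogeneity_trace = NULL,
                             bone_grown = NULL, background_grown = NULL) {
  structure(
    list(bone = bone, voi = voi, spacing_mm = spacing_mm, method = method,
         chosen_threshold = chosen_threshold,
         homogeneity_trace = homogeneity_trace,
         bone_grown = bone_grown, background_grown = background_grown),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> method %s, %d bone voxels (BV/TV %.3f)\n",
              x$method, sum(x$bone), sum(x$bone) / sum(x$voi$data)))
  if (!is.na(x$chosen_threshold)) {
    cat(sprintf("  chosen homogeneity threshold t = %.4g (x VOI SD)\n",
                x$chosen_threshold))
  }
  invisible(x)
}

#' Grow bone and background regions at one homogeneity threshold
#'
#' Bone seeds are the voxels in the top `seed_quantile_bone` intensity
#' quantile of the VOI, background seeds the bottom
#' `seed_quantile_background` quantile. The two regions then grow
#' alternately (bone first); a frontier voxel joins a region when its
#' intensity is within `t * sd(VOI)` of the running region mean, updated
#' incrementally. Voxels claimed by neither region when growth stalls are
#' assigned to the region with the nearer mean (ties to bone). The grown
#' regions before that final assignment are kept on the result
#' (`bone_grown`, `background_grown`); at `t -> 0` they reduce to the seeds.
#'
#' @param volume an [image_volume()].
#' @param voi a [mask_volume()] (or `NULL` for the whole volume).
#' @param t homogeneity threshold (> 0), multiples of the VOI intensity SD.
#' @param config an [arg_config()].
#' @return A `segmentation` object. Its homogeneity trace holds the scores of
#'   the final bone/background partition.
#' @export
grow_regions <- function(volume, voi = NULL, t, config = arg_config()) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0) stop("t must be > 0")
  if (is.null(voi)) {
    voi <- mask_volume(array(TRUE, dim(volume$data)), volume$spacing_mm)
  }
  check_same_lattice(volume, voi)
  if (!any(voi$data)) stop("empty VOI")
  vals_voi <- volume$data[voi$data]
  sd_voi <- stats::sd(vals_voi)
  if (!is.finite(sd_voi) || sd_voi == 0) stop("constant VOI; cannot grow regions")
  seeds <- arg_seeds(vals_voi, config)

  assign0 <- array(-1L, dim(volume$data))
  assign0[voi$data] <- 0L
  bone_seed <- voi$data & volume$data >= seeds$hi
  bg_seed <- voi$data & volume$data <= seeds$lo
  if (!any(bone_seed) || !any(bg_seed)) stop("empty seed set at the given quantiles")
  assign0[bone_seed] <- 1L
  assign0[bg_seed] <- 2L

  res <- cpp_grow_regions(as.numeric(volume$data), as.integer(assign0),
                          dim(volume$data), t * sd_voi,
                          config$connectivity, 10000L)
  assign <- array(res$assign, dim(volume$data))
  bone_grown <- assign == 1L
  background_grown <- assign == 2L
  unclaimed <- assign == 0L
  if (any(unclaimed)) {
    db <- abs(volume$data - res$mean_bone)
    dg <- abs(volume$data - res$mean_background)
    to_bone <- unclaimed & (db <= dg)      # ties go to bone (bone-first order)
    assign[to_bone] <- 1L
    assign[unclaimed & !to_bone] <- 2L
  }
  bone <- assign == 1L
  background <- assign == 2L
  h_bone <- if (any(bone)) homogeneity(volume, bone, voi) else 0
  h_bg <- if (any(background)) homogeneity(volume, background, voi) else 0
  trace <- data.frame(threshold = t, bone = h_bone, background = h_bg,
                      combined = (h_bone + h_bg) / 2)
  new_segmentation(bone, voi, volume$spacing_mm, method = "arg",
                   chosen_threshold = t, homogeneity_trace = trace,
                   bone_grown = bone_grown, background_grown = background_grown)
}

#' Automated region growing segmentation
#'
#' Runs [grow_regions()] for every threshold in the schedule and returns the
#' segmentation whose bone/background partition maximizes the combined
#' homogeneity score (unweighted mean of the two region scores; an empty
#' region scores 0). Ties take the first (smallest) threshold. The full
#' trace over the schedule is retained.
#'
#' @inheritParams grow_regions
#' @return A `segmentation` object with `chosen_threshold` and
#'   `homogeneity_trace` (one row per schedule entry).
#' @export
arg_segment <- function(volume, voi = NULL, config = arg_config()) {
  stopifnot(inherits(config, "arg_config"))
  best <- NULL
  trace <- vector("list", length(config$threshold_schedule))
  for (i in seq_along(config$threshold_schedule)) {
    t <- config$threshold_schedule[i]
    seg <- grow_regions(volume, voi, t, config)
    trace[[i]] <- seg$homogeneity_trace
    if (is.null(best) ||
        seg$homogeneity_trace$combined > best$homogeneity_trace$combined + 1e-12) {
      best <- seg
    }
  }
  best$homogeneity_trace <- do.call(rbind, trace)
  best
}

#' Otsu segmentation of a volume
#'
#' @inheritParams otsu_threshold
#' @return A `segmentation` object (bone = intensity above the threshold,
#'   restricted to the VOI).
#' @export
otsu_segment <- function(volume, voi = NULL, n_bins = 256L) {
  if (is.null(voi)) {
    voi <- mask_volume(array(TRUE, dim(volume$data)), volume$spacing_mm)
  }
  thr <- otsu_threshold(volume, voi, n_bins)
  bone <- voi$data & volume$data > thr
  new_segmentation(bone, voi, volume$spacing_mm, method = "otsu",
                   chosen_threshold = thr)
}
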