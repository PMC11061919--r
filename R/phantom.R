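#' Synthetic trabecular phantom specification
#'
#' Phantoms stand in for physical specimens: two-intensity volumes built from
#' plates and/or rods of known width and pitch, so every downstream measure
#' has an analytic ground truth. The base resolution must resolve the
#' elements (`base_spacing_mm <= element_width_mm / 3`).
#'
#' @param kind `"plate_stack"` (parallel plates normal to z),
#'   `"rod_lattice"` (rods along z on a square grid), or `"mixed"` (union of
#'   rod families along x, y and z, giving a connected lattice with nodes).
#' @param pitch_mm centre-to-centre repeat distance, mm.
#' @param element_width_mm plate thickness / rod diameter, mm.
#' @param extent_mm length-3 physical extent of the volume, mm.
#' @param base_spacing_mm voxel edge length, mm.
#' @param bone_intensity,background_intensity the two intensity levels.
#' @param rng_seed integer, recorded for provenance (generation itself is
#'   deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("plate_stack", "rod_lattice", "mixed"),
                         pitch_mm = 1.0, element_width_mm = 0.2,
                         extent_mm = c(4, 4, 4), base_spacing_mm = 0.05,
                         bone_intensity = 1000, background_intensity = 100,
                         rng_seed = 1L) {
  kind <- match.arg(kind)
  if (!(element_width_mm < pitch_mm)) {
    stop("unresolvable geometry: element_width_mm must be < pitch_mm")
  }
  if (!(base_spacing_mm <= element_width_mm / 3)) {
    stop("unresolvable geometry: base_spacing_mm must be <= element_width_mm / 3")
  }
  stopifnot(length(extent_mm) == 3, all(extent_mm > 0))
  structure(
    list(kind = kind, pitch_mm = pitch_mm,
         element_width_mm = element_width_mm,
         extent_mm = as.numeric(extent_mm),
         base_spacing_mm = base_spacing_mm,
         bone_intensity = bone_intensity,
         background_intensity = background_intensity,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

#' Generate a phantom volume with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return A list: `volume` (two-intensity [image_volume()]), `truth_mask`
#'   (binary bone phase as [mask_volume()]), and `truth` — analytic values
#'   `bvtv`, `tb_th_mm`, `tb_sp_mm`, `tb_sc_mm` implied by the geometry (for
#'   the mixed lattice the volume fraction is taken from the generated grid,
#'   since the three-family union has no closed form worth defending).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$base_spacing_mm
  dims <- pmax(1L, as.integer(round(spec$extent_mm / s)))
  cx <- (seq_len(dims[1]) - 0.5) * s
  cy <- (seq_len(dims[2]) - 0.5) * s
  cz <- (seq_len(dims[3]) - 0.5) * s
  p <- spec$pitch_mm
  w <- spec$element_width_mm
  r2 <- (w / 2)^2

  # Alignment conventions: plates are centred on multiples of the pitch, so
  # a volume whose extent is a whole number of pitches is cut through plate
  # mid-planes at its faces and every marrow gap is interior (no half-open
  # boundary gaps). Rod axes are offset by half a pitch so that rods — and,
  # for the mixed lattice, their junctions — lie away from the artificial
  # cut faces, where medial structure would be truncated.
  axis_dist <- function(a, offset = 0) {
    da <- (a - offset) %% p
    pmin(da, p - da)
  }
  rod_profile <- function(a, b) {
    # squared distance of (a, b) cross-section coords to nearest rod axis
    outer(axis_dist(a, p / 2)^2, axis_dist(b, p / 2)^2, "+")
  }
  bone <- array(FALSE, dims)
  if (spec$kind == "plate_stack") {
    in_plate <- axis_dist(cz) < w / 2
    bone[, , in_plate] <- TRUE
  } else {
    if (spec$kind %in% c("rod_lattice", "mixed")) {
      xy <- rod_profile(cx, cy) <= r2       # rods along z
      for (k in seq_len(dims[3])) bone[, , k] <- bone[, , k] | xy
    }
    if (spec$kind == "mixed") {
      yz <- rod_profile(cy, cz) <= r2       # rods along x
      for (i in seq_len(dims[1])) bone[i, , ] <- bone[i, , ] | yz
      xz <- rod_profile(cx, cz) <= r2       # rods along y
      for (j in seq_len(dims[2])) bone[, j, ] <- bone[, j, ] | xz
    }
  }

  truth_bvtv <- switch(spec$kind,
    plate_stack = w / p,
    rod_lattice = pi * (w / 2)^2 / p^2,
    mixed = mean(bone)
  )
  vol <- image_volume(
    array(spec$background_intensity +
            (spec$bone_intensity - spec$background_intensity) * bone, dims),
    s
  )
  list(
    volume = vol,
    truth_mask = mask_volume(bone, s),
    truth = list(bvtv = truth_bvtv, tb_th_mm = w, tb_sp_mm = p - w,
                 tb_sc_mm = p),
    spec = spec
  )
}

#' Scanner degradation specification
#'
#' Emulates the imaging chain between the fine binary truth and what a CT
#' device measures: an isotropic Gaussian point-spread blur, resampling to
#' the device voxel size (the partial-volume mechanism), and additive
#' Gaussian noise.
#'
#' @param psf_sigma_mm Gaussian PSF sigma in mm (>= 0).
#' @param target_spacing_mm output voxel size (>= input spacing).
#' @param noise_sd additive Gaussian noise SD, intensity units (>= 0).
#' @param rng_seed integer seed for the noise draw.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(psf_sigma_mm = 0, target_spacing_mm,
                             noise_sd = 0, rng_seed = 1L) {
  stopifnot(psf_sigma_mm >= 0, noise_sd >= 0, target_spacing_mm > 0)
  structure(
    list(psf_sigma_mm = psf_sigma_mm, target_spacing_mm = target_spacing_mm,
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "degradation_spec"
  )
}

#' Degrade a volume to scanner-like resolution and noise
#'
#' Blur (reflective boundaries), then resample to the target spacing (block
#' mean for integer ratios, trilinear otherwise), then add Gaussian noise.
#' Deterministic given `rng_seed`; with zero PSF, zero noise and unchanged
#' spacing it is the identity.
#'
#' @param volume an [image_volume()].
#' @param spec a [degradation_spec()].
#' @return A degraded [image_volume()].
#' @export
degrade <- function(volume, spec) {
  stopifnot(inherits(volume, "image_volume"), inherits(spec, "degradation_spec"))
  x <- volume
  if (spec$psf_sigma_mm > 0) {
    blurred <- cpp_gauss_blur(as.numeric(x$data), dim(x$data),
                              spec$psf_sigma_mm / x$spacing_mm)
    x <- image_volume(array(blurred, dim(x$data)), x$spacing_mm, x$origin)
  }
  x <- resample_to_spacing(x, spec$target_spacing_mm)
  if (spec$noise_sd > 0) {
    x <- add_scanner_noise(x, spec$noise_sd, spec$psf_sigma_mm,
                           spec$rng_seed)
  }
  x
}

# CT noise is correlated by the reconstruction kernel: draw white noise on
# the device grid, correlate it with the PSF, rescale to the calibrated SD
add_scanner_noise <- function(volume, noise_sd, psf_sigma_mm, rng_seed) {
  noise <- with_seed(rng_seed, stats::rnorm(length(volume$data)))
  if (psf_sigma_mm > 0) {
    noise <- cpp_gauss_blur(noise, dim(volume$data),
                            psf_sigma_mm / volume$spacing_mm)
  }
  noise <- noise * (noise_sd / stats::sd(noise))
  image_volume(volume$data + array(noise, dim(volume$data)),
               volume$spacing_mm, volume$origin)
}

resample_to_spacing <- function(volume, target_spacing_mm) {
  ratio <- target_spacing_mm / volume$spacing_mm
  if (ratio < 1 - 1e-9) {
    stop("target spacing finer than the input spacing; upsampling is not supported")
  }
  if (abs(ratio - 1) < 1e-9) return(volume)
  if (abs(ratio - round(ratio)) < 1e-9) {
    return(downsample_block(volume, as.integer(round(ratio))))
  }
  d <- dim(volume$data)
  newdim <- pmax(1L, as.integer(floor(d / ratio)))
  out <- cpp_resample_trilinear(as.numeric(volume$data), d, newdim, ratio)
  image_volume(array(out, newdim), target_spacing_mm, volume$origin)
}

#' Resample a binary mask to a coarser grid
#'
#' Trilinear resampling of the 0/1 field followed by thresholding at 0.5
#' (majority occupancy). Used to carry phantom ground truth onto degraded
#' lattices.
#'
#' @param mask a [mask_volume()].
#' @param target_spacing_mm output voxel size.
#' @return A [mask_volume()].
#' @export
resample_mask <- function(mask, target_spacing_mm) {
  v <- image_volume(array(as.numeric(mask$data), dim(mask$data)),
                    mask$spacing_mm)
  r <- resample_to_spacing(v, target_spacing_mm)
  mask_volume(r$data >= 0.5, r$spacing_mm)
}

#' Noise level that realizes a target CNR
#'
#' The devices in a validation study are characterized by their
#' contrast-to-noise ratio, not by a noise SD, so the phantom noise is
#' calibrated: given the blurred, resampled (noise-free) volume and its bone
#' truth on the same lattice, the additive-noise SD `n` is chosen so that
#' the predicted CNR `(mean_fg - mean_bg) / sqrt(sd_bg^2 + n^2)` (foreground
#' = skeletonized truth) matches `target_cnr`.
#'
#' @param volume noise-free degraded [image_volume()].
#' @param bone_mask truth bone [mask_volume()] on the same lattice.
#' @param target_cnr desired CNR (> 0).
#' @param background optional logical array of pure background voxels to
#'   calibrate against; defaults to the complement of `bone_mask`. At coarse
#'   voxel sizes the complement is contaminated by partial-volume voxels
#'   whose spread is not noise, so callers can pass marrow voxels well away
#'   from bone.
#' @return Noise SD in intensity units.
#' @export
noise_sd_for_cnr <- function(volume, bone_mask, target_cnr,
                             background = NULL) {
  stopifnot(target_cnr > 0)
  check_same_lattice(volume, bone_mask)
  skel <- skeletonize(bone_mask$data, volume$spacing_mm)
  fg <- skel$voxels
  bg <- if (is.null(background)) !bone_mask$data else background
  if (!any(bg)) stop("empty calibration background")
  contrast <- mean(volume$data[fg]) - mean(volume$data[bg])
  s0 <- stats::sd(volume$data[bg])
  v <- (contrast / target_cnr)^2 - s0^2
  if (v <= 0) {
    stop(sprintf(
      "target CNR %.3g unreachable: residual partial-volume spread alone gives CNR %.3g",
      target_cnr, contrast / s0))
  }
  sqrt(v)
}

#' Device presets for the degradation chain
#'
#' Voxel size, PSF width (0.6 x voxel size) and target CNR for the three
#' working resolutions of a micro-CT / HR-pQCT comparison: micro-CT at
#' 32.8 um (CNR 12.57) and HR-pQCT at 61 um (CNR 6.98) and 82 um (CNR 6.68).
#'
#' @param name `"microct32"`, `"hr61"` or `"lr82"`.
#' @return list with `target_spacing_mm`, `psf_sigma_mm`, `target_cnr`.
#' @export
scanner_preset <- function(name = c("microct32", "hr61", "lr82")) {
  name <- match.arg(name)
  sp <- switch(name, microct32 = 0.0328, hr61 = 0.061, lr82 = 0.082)
  cnr <- switch(name, microct32 = 12.57, hr61 = 6.98, lr82 = 6.68)
  list(name = name, target_spacing_mm = sp, psf_sigma_mm = 0.6 * sp,
       target_cnr = cnr)
}

#' Degrade a phantom with a device preset
#'
#' Applies the preset's blur and resampling, calibrates additive noise to
#' the preset CNR with [noise_sd_for_cnr()], and adds it.
#'
#' @param phantom output of [make_phantom()].
#' @param preset a preset name or [scanner_preset()] list.
#' @param rng_seed seed for the noise draw.
#' @return list: `volume` (degraded [image_volume()]), `truth_mask` (truth
#'   resampled to the degraded lattice), `noise_sd`.
#' @export
degrade_with_preset <- function(phantom, preset = "hr61", rng_seed = 1L) {
  if (is.character(preset)) preset <- scanner_preset(preset)
  clean <- degrade(phantom$volume,
                   degradation_spec(preset$psf_sigma_mm,
                                    preset$target_spacing_mm, 0))
  # continuous bone occupancy on the degraded lattice: threshold at 0.5 for
  # the truth mask, and use nearly bone-free voxels (< 5% occupancy) as the
  # pure-marrow background for the noise calibration
  occ <- resample_to_spacing(
    image_volume(array(as.numeric(phantom$truth_mask$data),
                       dim(phantom$truth_mask$data)),
                 phantom$truth_mask$spacing_mm),
    preset$target_spacing_mm
  )
  stopifnot(identical(dim(occ$data), dim(clean$data)))
  truth <- mask_volume(occ$data >= 0.5, occ$spacing_mm)
  pure_bg <- occ$data < 0.05
  nsd <- noise_sd_for_cnr(clean, truth, preset$target_cnr,
                          background = pure_bg)
  noisy <- add_scanner_noise(clean, nsd, preset$psf_sigma_mm, rng_seed)
  list(volume = noisy, truth_mask = truth, noise_sd = nsd, preset = preset)
}

#' Synthetic specimen cohort
#'
#' Generates `n` phantoms with element widths and pitches drawn uniformly
#' from the stated ranges, each delivered at the reference (base) resolution
#' and once degraded with a device preset — the in-silico analogue of a
#' paired micro-CT / HR-pQCT specimen study.
#'
#' @param n number of specimens (>= 3).
#' @param width_range,pitch_range uniform sampling ranges in mm. Degenerate
#'   (zero-width) ranges are allowed but flagged with a warning, since
#'   identical truths make downstream correlations undefined.
#' @param kind phantom kind (see [phantom_spec()]).
#' @param base_spacing_mm reference voxel size.
#' @param extent_mm cubic extent of each specimen, mm.
#' @param preset degradation preset (see [scanner_preset()]).
#' @param rng_seed master seed; all per-specimen randomness derives from it.
#' @return list of class `specimen_cohort`; each element has `id`,
#'   `reference` ([image_volume()]), `truth_mask`, `truth`, `degraded`
#'   (list from [degrade_with_preset()]), `width_mm`, `pitch_mm`.
#' @export
specimen_cohort <- function(n = 23, width_range = c(0.10, 0.20),
                            pitch_range = c(0.7, 1.1), kind = "mixed",
                            base_spacing_mm = 0.0328, extent_mm = 2.6,
                            preset = "hr61", rng_seed = 1L) {
  stopifnot(n >= 3)
  if (diff(range(width_range)) <= 0 && diff(range(pitch_range)) <= 0) {
    warning("degenerate ranges: all specimens share one geometry; ",
            "downstream correlations will be undefined")
  }
  draws <- with_seed(rng_seed, list(
    w = stats::runif(n, width_range[1], width_range[2]),
    p = stats::runif(n, pitch_range[1], pitch_range[2])
  ))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(kind = kind, pitch_mm = draws$p[i],
                         element_width_mm = draws$w[i],
                         extent_mm = rep(extent_mm, 3),
                         base_spacing_mm = base_spacing_mm,
                         rng_seed = rng_seed + i)
    ph <- make_phantom(spec)
    deg <- degrade_with_preset(ph, preset, rng_seed = rng_seed + i)
    out[[i]] <- list(id = sprintf("S%02d", i), reference = ph$volume,
                     truth_mask = ph$truth_mask, truth = ph$truth,
                     degraded = deg, width_mm = draws$w[i],
                     pitch_mm = draws$p[i])
  }
  structure(out, class = "specimen_cohort", rng_seed = rng_seed)
}

# run code with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Dice overlap coefficient between two binary arrays
#'
#' @param a,b logical arrays of the same shape.
#' @return `2|a & b| / (|a| + |b|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  a <- as_volume_array(a) != 0
  b <- as_volume_array(b) != 0
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
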