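#' Bone volume fraction
#'
#' Number of voxels segmented as bone divided by the number of voxels in the
#' volume of interest (integer arithmetic; exact on binary inputs).
#'
#' @param seg a `segmentation` (from [arg_segment()], [otsu_segment()] or
#'   built manually with bone and VOI arrays).
#' @return Fraction in `[0, 1]`.
#' @export
bvtv <- function(seg) {
  n_voi <- sum(seg$voi$data)
  if (n_voi == 0L) stop("empty VOI")
  sum(seg$bone & seg$voi$data) / n_voi
}

#' Skeletonize the bone phase
#'
#' One-voxel-wide medial representation via sequential topology-preserving
#' 3D thinning (simple points only are removed, in six directional
#' subiterations; curve endpoints are preserved). The number of 26-connected
#' components is preserved, and one-voxel-thick plates survive as medial
#' surfaces. Structures are assumed to continue beyond the volume faces, so
#' nothing is eroded from the artificial VOI cut.
#'
#' @param seg a `segmentation`, or a logical array plus `spacing_mm`.
#' @param spacing_mm voxel spacing, required when `seg` is a plain array.
#' @return An object of class `skeleton` with fields `voxels` (logical
#'   array) and `spacing_mm`.
#' @export
skeletonize <- function(seg, spacing_mm = NULL) {
  if (inherits(seg, "segmentation")) {
    bone <- seg$bone
    spacing_mm <- seg$spacing_mm
  } else {
    bone <- as_volume_array(seg) != 0
    if (is.null(spacing_mm)) stop("spacing_mm required for a plain array")
  }
  vox <- array(cpp_skeletonize(as.logical(bone), dim(bone)), dim(bone))
  structure(list(voxels = vox, spacing_mm = spacing_mm), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d voxels on a %s grid\n", sum(x$voxels),
              paste(dim(x$voxels), collapse = " x ")))
  invisible(x)
}

#' Local thickness map (maximal inscribed sphere)
#'
#' For each structure voxel, the diameter in mm of the largest sphere that
#' lies entirely inside the structure and contains the voxel. The sphere
#' radius is the Euclidean distance to the phase boundary (distance to the
#' nearest background voxel centre minus half a voxel), so an isolated voxel
#' measures exactly one voxel and a slab of k voxels measures `k * spacing`.
#' Structures are assumed to continue beyond the grid faces. If the
#' structure fills the whole grid, the largest sphere inscribed in the grid
#' box is used.
#'
#' @param structure logical 3D array (non-empty).
#' @param spacing_mm voxel edge length in mm.
#' @param kind one of `"thickness"`, `"spacing"`, `"separation"` (label
#'   only).
#' @return An object of class `local_map`: `values` (array, mm; 0 off the
#'   support), `support` (logical array), `kind`, `spacing_mm`.
#' @export
local_thickness <- function(structure, spacing_mm,
                            kind = c("thickness", "spacing", "separation")) {
  kind <- match.arg(kind)
  structure <- as_volume_array(structure) != 0
  if (!any(structure)) stop("empty structure")
  d <- dim(structure)
  if (all(structure)) {
    # degenerate: no complement; largest sphere inscribed in the grid box
    diam <- min(d) * spacing_mm
    values <- array(diam, d)
  } else {
    vox <- array(cpp_local_thickness(as.logical(structure), d), d)
    values <- vox * spacing_mm
  }
  values[!structure] <- 0
  structure(list(values = values, support = structure, kind = kind,
                 spacing_mm = spacing_mm),
            class = "local_map")
}

#' @export
print.local_map <- function(x, ...) {
  v <- x$values[x$support]
  cat(sprintf("<local_map> %s: %d voxels, mean %.4g mm, sd %.4g mm\n",
              x$kind, length(v), mean(v), stats::sd(v)))
  invisible(x)
}

map_mean_sd <- function(map, sample_set = NULL) {
  sel <- if (is.null(sample_set)) map$support else sample_set
  v <- map$values[sel]
  c(mean = mean(v), sd = if (length(v) < 2L) 0 else stats::sd(v))
}

#' Trabecular thickness Tb.Th
#'
#' Mean (and intra-volume sample SD) of the bone local thickness map over
#' bone voxels, in mm.
#'
#' @param seg a `segmentation` with non-empty bone phase.
#' @return Named numeric `c(mean, sd)` in mm.
#' @export
tb_th <- function(seg) {
  bone <- seg$bone & seg$voi$data
  if (!any(bone)) stop("empty bone phase")
  map_mean_sd(local_thickness(bone, seg$spacing_mm, "thickness"))
}

#' Trabecular separation Tb.Sp
#'
#' Local thickness of the marrow phase (complement of bone): the minimum
#' edge-to-edge distance between neighbouring trabeculae, averaged (with
#' sample SD) over the VOI background voxels, in mm. The marrow space is
#' assumed to continue beyond the VOI cut, so cropping to the VOI bounding
#' box and masking inside it give the same numbers.
#'
#' @inheritParams tb_th
#' @return Named numeric `c(mean, sd)` in mm.
#' @export
tb_sp <- function(seg) {
  bg <- seg$voi$data & !seg$bone
  if (!any(bg)) stop("empty background phase")
  map <- local_thickness(!seg$bone, seg$spacing_mm, "separation")
  map_mean_sd(map, sample_set = bg)
}

#' Trabecular spacing Tb.Sc
#'
#' Midline-to-midline distance between neighbouring trabeculae: the local
#' thickness of the complement of the skeleton within the VOI, averaged
#' (with sample SD) over background voxels, in mm. By construction
#' `Tb.Sc >= Tb.Sp` on every input.
#'
#' @param seg a `segmentation`.
#' @param skel the matching [skeletonize()] output (computed when `NULL`).
#' @return Named numeric `c(mean, sd)` in mm.
#' @export
tb_sc <- function(seg, skel = NULL) {
  if (is.null(skel)) skel <- skeletonize(seg)
  if (!any(skel$voxels)) stop("empty skeleton")
  bg <- seg$voi$data & !seg$bone
  if (!any(bg)) stop("empty background phase")
  map <- local_thickness(!skel$voxels, seg$spacing_mm, "spacing")
  map_mean_sd(map, sample_set = bg)
}

skeleton_degrees <- function(skel) {
  array(cpp_neighbor_count26(as.logical(skel$voxels), dim(skel$voxels)),
        dim(skel$voxels))
}

#' Trabecular node density Tb.Nd
#'
#' Skeleton intersections per mm^3: 26-connected clusters of skeleton voxels
#' with at least three skeleton neighbours, counted as one node each,
#' divided by the VOI volume.
#'
#' @param skel a `skeleton`.
#' @param voi a [mask_volume()] (defines the reference volume).
#' @return Nodes per mm^3.
#' @export
tb_nd <- function(skel, voi) {
  n_voi <- sum(voi$data)
  if (n_voi == 0L) stop("empty VOI")
  deg <- skeleton_degrees(skel)
  nodes <- skel$voxels & deg >= 3L
  n_clusters <- if (any(nodes)) max(cpp_label26(as.logical(nodes), dim(nodes))) else 0L
  n_clusters / (n_voi * skel$spacing_mm^3)
}

#' Trabecular terminus density Tb.Tm
#'
#' Free skeleton ends per mm^3: skeleton voxels with exactly one skeleton
#' neighbour (26-connectivity), divided by the VOI volume.
#'
#' @inheritParams tb_nd
#' @return Termini per mm^3.
#' @export
tb_tm <- function(skel, voi) {
  n_voi <- sum(voi$data)
  if (n_voi == 0L) stop("empty VOI")
  deg <- skeleton_degrees(skel)
  sum(skel$voxels & deg == 1L) / (n_voi * skel$spacing_mm^3)
}

#' Contrast-to-noise ratio
#'
#' Difference in mean intensity between the foreground (skeletonized bone)
#' and the background, divided by the standard deviation of the background
#' intensities. The background defaults to VOI minus bone (marrow).
#'
#' @param volume the grayscale [image_volume()].
#' @param skel a `skeleton` (foreground sample).
#' @param background logical array of background voxels.
#' @return Unitless CNR.
#' @export
cnr <- function(volume, skel, background) {
  fg <- skel$voxels
  background <- as_volume_array(background) != 0
  if (!any(fg)) stop("empty skeleton foreground")
  if (!any(background)) stop("empty background")
  sd_bg <- stats::sd(volume$data[background])
  if (!is.finite(sd_bg) || sd_bg == 0) stop("zero background SD; CNR undefined")
  (mean(volume$data[fg]) - mean(volume$data[background])) / sd_bg
}

#' Full morphometric analysis of one volume
#'
#' Segments the volume (ARG or Otsu), skeletonizes the bone phase, and
#' computes the nine bone structure parameters plus CNR: BVTV, Tb.Th,
#' s(Tb.Th), Tb.Sc, s(Tb.Sc), Tb.Sp, s(Tb.Sp), Tb.Nd, Tb.Tm, CNR.
#'
#' @param volume an [image_volume()].
#' @param voi a [mask_volume()] (`NULL` = whole volume).
#' @param method `"arg"` or `"otsu"`.
#' @param config [arg_config()] for the ARG path.
#' @param n_bins histogram bins for the Otsu path.
#' @return An object of class `morphometry_result`.
#' @export
analyze <- function(volume, voi = NULL, method = c("arg", "otsu"),
                    config = arg_config(), n_bins = 256L) {
  method <- match.arg(method)
  if (is.null(voi)) {
    voi <- mask_volume(array(TRUE, dim(volume$data)), volume$spacing_mm)
  } else {
    # restrict to the VOI bounding box so that cropping before analysis and
    # masking inside it are the same computation
    cropped <- extract_voi(volume, voi)
    volume <- cropped$volume
    voi <- cropped$mask
  }
  seg <- if (method == "arg") arg_segment(volume, voi, config)
         else otsu_segment(volume, voi, n_bins)
  morphometry(volume, seg)
}

#' Morphometry of an existing segmentation
#'
#' @param volume the grayscale [image_volume()] (used for CNR).
#' @param seg a `segmentation`.
#' @param skel optional precomputed `skeleton`.
#' @return An object of class `morphometry_result`.
#' @export
morphometry <- function(volume, seg, skel = NULL) {
  if (is.null(skel)) skel <- skeletonize(seg)
  th <- tb_th(seg)
  sp <- tb_sp(seg)
  sc <- tb_sc(seg, skel)
  bg <- seg$voi$data & !seg$bone
  # noise-free volumes have zero background SD: report Inf rather than fail
  cnr_val <- if (any(bg) && stats::sd(volume$data[bg]) == 0) {
    contrast <- mean(volume$data[skel$voxels]) - mean(volume$data[bg])
    if (contrast == 0) NA_real_ else Inf * sign(contrast)
  } else {
    cnr(volume, skel, bg)
  }
  structure(
    list(
      bvtv = bvtv(seg),
      tb_th_mm = unname(th["mean"]), s_tb_th_mm = unname(th["sd"]),
      tb_sc_mm = unname(sc["mean"]), s_tb_sc_mm = unname(sc["sd"]),
      tb_sp_mm = unname(sp["mean"]), s_tb_sp_mm = unname(sp["sd"]),
      tb_nd_per_mm3 = tb_nd(skel, seg$voi),
      tb_tm_per_mm3 = tb_tm(skel, seg$voi),
      cnr = cnr_val,
      method = seg$method,
      chosen_threshold = seg$chosen_threshold,
      spacing_mm = seg$spacing_mm
    ),
    class = "morphometry_result"
  )
}

#' Column order of exported morphometry tables
#' @export
morphometry_columns <- function() {
  c("BVTV", "Tb.Th", "s(Tb.Th)", "Tb.Sc", "s(Tb.Sc)", "Tb.Sp", "s(Tb.Sp)",
    "Tb.Nd", "Tb.Tm", "CNR")
}

#' @export
as.data.frame.morphometry_result <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  d <- data.frame(
    x$bvtv, x$tb_th_mm, x$s_tb_th_mm, x$tb_sc_mm, x$s_tb_sc_mm,
    x$tb_sp_mm, x$s_tb_sp_mm, x$tb_nd_per_mm3, x$tb_tm_per_mm3, x$cnr,
    check.names = FALSE
  )
  names(d) <- morphometry_columns()
  d
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> (%s segmentation, %.4g mm voxels)\n",
              x$method, x$spacing_mm))
  d <- as.data.frame(x)
  print(round(as.data.frame(t(d)), 4))
  invisible(x)
}
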