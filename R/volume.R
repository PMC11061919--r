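#' 3D grayscale volume with isotropic voxel spacing
#'
#' The unit every stage of the pipeline consumes: a 3D numeric array indexed
#' `[x, y, z]` (1-based, x fastest, R's native column-major order) together
#' with the isotropic voxel edge length in millimetres. Formats that store
#' data in a different axis order are rearranged on load.
#'
#' @param data 3D numeric array of intensities (arbitrary units). All values
#'   must be finite.
#' @param spacing_mm positive scalar, isotropic voxel edge length in mm.
#' @param origin numeric length-3, position of the first voxel in mm
#'   (informational only).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm, origin = c(0, 0, 0)) {
  data <- as_volume_array(data)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0) {
    stop("spacing_mm must be a single positive number (mm)")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("volume intensities must be finite (no NA/NaN/Inf)")
  }
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' Binary mask on the lattice of an image volume
#'
#' Used both for the trabecular volume of interest (cortical bone already
#' excluded) and for bone/background segmentations.
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param spacing_mm isotropic voxel edge length in mm.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, spacing_mm) {
  data <- as_volume_array(data)
  if (is.numeric(data)) {
    bad <- !(data %in% c(0, 1))
    if (any(bad)) stop("mask values must be 0/1 or logical")
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask must be logical or 0/1")
  if (anyNA(data)) stop("mask must not contain NA")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    stop("spacing_mm must be a single positive number (mm)")
  }
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm)),
            class = "mask_volume")
}

as_volume_array <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("data must be a 3D array")
  }
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  # strip foreign classes/attributes (e.g. niftiImage) down to a plain array
  array(as.vector(data), dim = dim(data))
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %.4g mm (%.4g um)\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing_mm, 1000 * x$spacing_mm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels, spacing %.4g mm, %d set (%.1f%%)\n",
              paste(dim(x$data), collapse = " x "), x$spacing_mm,
              sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

check_same_lattice <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data))) {
    stop("volume and mask shapes differ: ",
         paste(dim(volume$data), collapse = "x"), " vs ",
         paste(dim(mask$data), collapse = "x"))
  }
  # 1e-6 relative: NIfTI stores pixdim as 32-bit floats
  if (abs(volume$spacing_mm - mask$spacing_mm) >
      1e-6 * max(volume$spacing_mm, mask$spacing_mm)) {
    stop("volume and mask voxel spacings differ")
  }
  invisible(TRUE)
}

check_isotropic <- function(spacings) {
  spacings <- as.numeric(spacings)
  if (length(spacings) < 3L || any(!is.finite(spacings)) || any(spacings <= 0)) {
    stop("missing or invalid voxel spacing metadata; supply spacing_mm")
  }
  s <- spacings[1:3]
  if (diff(range(s)) > 1e-4 * mean(s)) {
    stop(sprintf("anisotropic voxel spacing (%s mm) is not supported",
                 paste(signif(s, 4), collapse = ", ")))
  }
  s[1]
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(mhd|mha)$", lp)) return("metaimage")
  if (grepl("\\.(tif|tiff)$", lp) || dir.exists(path)) return("tiff_stack")
  stop("cannot guess volume format from path: ", path)
}

#' Read a 3D volume
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mhd` + `.raw`,
#' or self-contained `.mha`), and TIFF stacks (one multi-page file, or a
#' directory of per-slice `.tif` files read in lexicographic order).
#' Intensities are cast to double. Voxel spacing must be isotropic; TIFF
#' carries no spacing so `spacing_mm` (or a JSON sidecar written by
#' [write_volume()]) is required.
#'
#' @param path file (or, for per-slice TIFF, directory) to read.
#' @param format one of `"nifti"`, `"metaimage"`, `"tiff_stack"`; guessed
#'   from the extension when `NULL`.
#' @param spacing_mm optional spacing override in mm (required for TIFF
#'   input without a sidecar).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = NULL, spacing_mm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- guess_format(path)
  format <- match.arg(format, c("nifti", "metaimage", "tiff_stack"))
  switch(format,
    nifti = read_nifti_volume(path, spacing_mm),
    metaimage = read_metaimage_volume(path, spacing_mm),
    tiff_stack = read_tiff_volume(path, spacing_mm)
  )
}

#' Read a binary mask volume
#'
#' Reads with [read_volume()] and converts to a [mask_volume()]; any nonzero
#' intensity counts as set.
#' @inheritParams read_volume
#' @export
read_mask <- function(path, format = NULL, spacing_mm = NULL) {
  v <- read_volume(path, format, spacing_mm)
  mask_volume(v$data != 0, v$spacing_mm)
}

#' Write a 3D volume
#'
#' @param volume an [image_volume()] or [mask_volume()] (masks are written
#'   as 0/1).
#' @param path output path; extension selects the format unless `format`
#'   is given.
#' @param format see [read_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = NULL) {
  if (inherits(volume, "mask_volume")) {
    volume <- image_volume(array(as.numeric(volume$data), dim(volume$data)),
                           volume$spacing_mm)
  }
  stopifnot(inherits(volume, "image_volume"))
  if (is.null(format)) format <- guess_format(path)
  format <- match.arg(format, c("nifti", "metaimage", "tiff_stack"))
  switch(format,
    nifti = write_nifti_volume(volume, path),
    metaimage = write_metaimage_volume(volume, path),
    tiff_stack = write_tiff_volume(volume, path)
  )
  invisible(path)
}

read_nifti_volume <- function(path, spacing_mm = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  s <- if (is.null(spacing_mm)) check_isotropic(RNifti::pixdim(img)) else spacing_mm
  image_volume(array(as.numeric(img), dim(img)), s)
}

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- rep(volume$spacing_mm, 3)
  RNifti::writeNifti(img, path, datatype = "double")
}

# --- MetaImage: plain-text header (+ raw little-endian block) -------------

read_metaimage_volume <- function(path, spacing_mm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("malformed MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3")) stop("only 3D MetaImage supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "", "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  msb <- toupper(hdr[["ElementByteOrderMSB"]] %||% "FALSE") == "TRUE"
  if (msb) stop("big-endian MetaImage not supported")
  rb <- switch(type,
    MET_FLOAT = function(con, n) readBin(con, "numeric", n, size = 4),
    MET_DOUBLE = function(con, n) readBin(con, "numeric", n, size = 8),
    MET_UCHAR = function(con, n) readBin(con, "integer", n, size = 1, signed = FALSE),
    MET_SHORT = function(con, n) readBin(con, "integer", n, size = 2, signed = TRUE),
    MET_USHORT = function(con, n) readBin(con, "integer", n, size = 2, signed = FALSE),
    MET_INT = function(con, n) readBin(con, "integer", n, size = 4),
    stop("unsupported MetaImage ElementType: ", type)
  )
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    vals <- rb(con, n)
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path)
    con2 <- file(raw_path, "rb")
    on.exit(close(con2), add = TRUE)
    vals <- rb(con2, n)
  }
  if (length(vals) != n) stop("truncated MetaImage data: ", path)
  s <- if (is.null(spacing_mm)) check_isotropic(sp) else spacing_mm
  image_volume(array(as.numeric(vals), dim = dims), s)
}

write_metaimage_volume <- function(volume, path) {
  dims <- dim(volume$data)
  local <- grepl("\\.mha$", tolower(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "ElementByteOrderMSB = False",
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementSpacing =", paste(rep(volume$spacing_mm, 3), collapse = " ")),
    "ElementType = MET_DOUBLE"
  )
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(volume$data), con, size = 8)
  } else {
    raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    writeLines(c(hdr, paste("ElementDataFile =", raw_name)), path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume$data), con, size = 8)
  }
}

# --- TIFF stacks ----------------------------------------------------------
# TIFF stores 32-bit float samples in [0, 1] only, so intensities are
# affinely rescaled on write and the scale + spacing recorded in a JSON
# sidecar (<path>.json). Foreign TIFFs without a sidecar are read with
# libtiff's [0, 1] normalization for integer data (every downstream measure
# is invariant under that affine rescaling) and need an explicit spacing.

tiff_sidecar <- function(path) paste0(path, ".json")

read_tiff_volume <- function(path, spacing_mm = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no .tif slices found in directory: ", path)
    slices <- lapply(files, function(f) tiff::readTIFF(f))
    side <- tiff_sidecar(files[1])
  } else {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    side <- tiff_sidecar(path)
  }
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  nz <- length(slices)
  d <- dim(slices[[1]])
  # slices arrive as [row = y, col = x]; stack into [x, y, z]
  arr <- array(0, dim = c(d[2], d[1], nz))
  for (i in seq_len(nz)) arr[, , i] <- t(slices[[i]])
  if (!is.null(meta$scale)) arr <- arr * meta$scale + meta$offset
  s <- spacing_mm %||% meta$spacing_mm
  if (is.null(s)) {
    stop("TIFF carries no voxel spacing; pass spacing_mm (or --spacing-um)")
  }
  image_volume(arr, s)
}

write_tiff_volume <- function(volume, path) {
  rng <- range(volume$data)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  offset <- rng[1]
  norm <- (volume$data - offset) / scale
  nz <- dim(volume$data)[3]
  slices <- lapply(seq_len(nz), function(i) t(norm[, , i]))
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(spacing_mm = volume$spacing_mm, scale = scale, offset = offset),
    tiff_sidecar(path), auto_unbox = TRUE, digits = NA
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict a volume to its volume of interest
#'
#' Crops volume and mask to the bounding box of the mask. Downstream
#' statistics only ever sample voxels where the returned mask is set, so
#' out-of-VOI voxels inside the box never contribute.
#'
#' @param volume an [image_volume()].
#' @param mask a [mask_volume()] on the same lattice with at least one voxel
#'   set.
#' @return list with elements `volume` (cropped [image_volume()]) and `mask`
#'   (cropped [mask_volume()]).
#' @export
extract_voi <- function(volume, mask) {
  check_same_lattice(volume, mask)
  if (!any(mask$data)) stop("empty VOI mask")
  idx <- which(mask$data, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  sel <- lapply(1:3, function(a) rng[1, a]:rng[2, a])
  cropped <- volume$data[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  mcropped <- mask$data[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  list(
    volume = image_volume(cropped, volume$spacing_mm, volume$origin),
    mask = mask_volume(mcropped, volume$spacing_mm)
  )
}

#' Block-average downsampling
#'
#' Each output voxel is the arithmetic mean of the corresponding
#' `factor^3` input block; the voxel spacing is multiplied by `factor`.
#' Trailing voxels that do not fill a complete block are dropped, so no
#' intensities are invented. The standard micro-CT memory reduction from
#' 16.4 to 32.8 um voxels corresponds to `factor = 2`.
#'
#' @param volume an [image_volume()].
#' @param factor positive integer block edge length.
#' @return A downsampled [image_volume()].
#' @export
downsample_block <- function(volume, factor) {
  stopifnot(inherits(volume, "image_volume"))
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor)) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(volume)
  d <- dim(volume$data)
  if (any(d < factor)) stop("each dimension must be >= factor")
  keep <- (d %/% factor) * factor
  x <- volume$data[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                   drop = FALSE]
  for (axis in 1:3) x <- block_mean_axis(x, factor, axis)
  image_volume(x, volume$spacing_mm * factor, volume$origin)
}

block_mean_axis <- function(x, f, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  y <- aperm(x, perm)
  dy <- dim(y)
  m <- matrix(y, nrow = f)
  means <- colMeans(m)
  y2 <- array(means, dim = c(dy[1] %/% f, dy[2], dy[3]))
  aperm(y2, order(perm))
}
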