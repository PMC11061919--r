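# Independent oracles and small fixture builders used across the suite.

# Brute-force maximal-inscribed-sphere local thickness on a small grid.
# For every structure voxel c, m(c) = Euclidean distance (voxel units) to the
# nearest non-structure voxel within the grid (structure is assumed to
# continue beyond the faces); sphere radius r(c) = max(m(c) - 0.5, 0.5).
# th(x) = 2 * max{ r(c) : |x - c| <= r(c) } * spacing.
brute_local_thickness <- function(structure, spacing_mm) {
  d <- dim(structure)
  idx <- which(structure, arr.ind = TRUE)
  bgx <- which(!structure, arr.ind = TRUE)
  stopifnot(nrow(idx) > 0, nrow(bgx) > 0)
  m <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    dif <- sweep(bgx, 2, idx[i, ])
    m[i] <- sqrt(min(rowSums(dif^2)))
  }
  r <- pmax(m - 0.5, 0.5)
  th <- array(0, d)
  for (i in seq_len(nrow(idx))) {
    dif <- sweep(idx, 2, idx[i, ])
    inside <- rowSums(dif^2) <= r[i]^2 + 1e-9
    sel <- idx[inside, , drop = FALSE]
    v <- 2 * r[i] * spacing_mm
    for (j in seq_len(nrow(sel))) {
      th[sel[j, 1], sel[j, 2], sel[j, 3]] <-
        max(th[sel[j, 1], sel[j, 2], sel[j, 3]], v)
    }
  }
  th
}

# Exhaustive 26-neighbour counts (out-of-grid voxels unset).
brute_neighbor_counts <- function(mask) {
  d <- dim(mask)
  cnt <- array(0L, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    c0 <- 0L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      if (mask[x2, y2, z2]) c0 <- c0 + 1L
    }
    cnt[x, y, z] <- c0
  }
  cnt
}

# 26-connected component count by BFS (independent of the C++ labeller).
brute_n_components <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  ncomp <- 0L
  coords <- which(mask, arr.ind = TRUE)
  key <- function(v) paste(v, collapse = ",")
  set <- new.env(hash = TRUE)
  for (i in seq_len(nrow(coords))) assign(key(coords[i, ]), TRUE, envir = set)
  for (i in seq_len(nrow(coords))) {
    p <- coords[i, ]
    if (seen[p[1], p[2], p[3]]) next
    ncomp <- ncomp + 1L
    queue <- list(p)
    seen[p[1], p[2], p[3]] <- TRUE
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        n <- q + c(dx, dy, dz)
        if (any(n < 1) || any(n > d)) next
        if (mask[n[1], n[2], n[3]] && !seen[n[1], n[2], n[3]]) {
          seen[n[1], n[2], n[3]] <- TRUE
          queue <- c(queue, list(n))
        }
      }
    }
  }
  ncomp
}

# hand-built skeleton fixtures on a cube grid ----------------------------

# straight open line along x through the centre
fix_line <- function(n = 11) {
  a <- array(FALSE, c(n, n, n))
  a[2:(n - 1), (n + 1) %/% 2, (n + 1) %/% 2] <- TRUE
  a
}

# closed rectangular loop in the central z-plane
fix_loop <- function(n = 11) {
  a <- array(FALSE, c(n, n, n))
  k <- (n + 1) %/% 2
  a[3:(n - 2), 3, k] <- TRUE
  a[3:(n - 2), n - 2, k] <- TRUE
  a[3, 3:(n - 2), k] <- TRUE
  a[n - 2, 3:(n - 2), k] <- TRUE
  a
}

# 3D plus sign: three orthogonal lines crossing once in the centre
fix_plus <- function(n = 11) {
  a <- array(FALSE, c(n, n, n))
  k <- (n + 1) %/% 2
  a[2:(n - 1), k, k] <- TRUE
  a[k, 2:(n - 1), k] <- TRUE
  a[k, k, 2:(n - 1)] <- TRUE
  a
}

# two disjoint plus signs (double cross)
fix_double_cross <- function(n = 23) {
  a <- array(FALSE, c(n, n, n))
  half <- fix_plus(11)
  a[1:11, 1:11, 1:11] <- half
  a[13:23, 13:23, 13:23] <- half
  a
}

# a VOI mask whose physical volume is exactly `mm3` cubic millimetres
voi_of_volume <- function(dims, spacing_mm, mm3) {
  n <- round(mm3 / spacing_mm^3)
  stopifnot(n <= prod(dims))
  m <- array(FALSE, dims)
  m[seq_len(n)] <- TRUE
  mask_volume(m, spacing_mm)
}

# quick two-intensity plate phantom helper
small_plate_phantom <- function(spacing = 0.05, pitch = 1, width = 0.2,
                                extent = 2) {
  make_phantom(phantom_spec("plate_stack", pitch_mm = pitch,
                            element_width_mm = width,
                            extent_mm = rep(extent, 3),
                            base_spacing_mm = spacing))
}

seg_from_arrays <- function(bone, spacing_mm, voi = NULL) {
  if (is.null(voi)) voi <- array(TRUE, dim(bone))
  trabmorph:::new_segmentation(bone, mask_volume(voi, spacing_mm), spacing_mm,
                               method = "manual")
}
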