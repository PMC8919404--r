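#' Rotation specification
#'
#' @param mode `"none"`, `"principal_inertia"` (align the segment's long
#'   axis, from its moments of inertia, with the slicing axis) or `"euler"`.
#' @param euler_angles_deg Rotations about x, then y, then z, in degrees
#'   (required for `mode = "euler"`).
#' @param center Rotation center in mm; default the foreground centroid.
#' @return An object of class `rotation_spec`.
#' @export
rotation_spec <- function(mode = c("none", "principal_inertia", "euler"),
                          euler_angles_deg = NULL, center = NULL) {
  mode <- match.arg(mode)
  if (mode == "euler") {
    if (is.null(euler_angles_deg) || length(euler_angles_deg) != 3L ||
        any(!is.finite(euler_angles_deg)))
      stop("mode = 'euler' requires three finite angles (degrees)",
           call. = FALSE)
  }
  structure(list(mode = mode,
                 euler_angles_deg = as.numeric(euler_angles_deg),
                 center = center),
            class = "rotation_spec")
}

.foreground_coords_mm <- function(mask) {
  idx <- which(mask$voxels != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("segment mask is empty", call. = FALSE)
  sweep(idx - 0.5, 2, mask$spacing, `*`)  # voxel centers
}

.rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                            c(0, sin(a), cos(a)))
.rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                            c(-sin(a), 0, cos(a)))
.rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                            c(0, 0, 1))

#' Principal inertia axes of a 3D segment
#'
#' Computes the covariance matrix of the foreground voxel center
#' coordinates (mm) and eigen-decomposes it. The eigenvector of largest
#' variance -- equivalently the axis of smallest moment of inertia, i.e.
#' the segment's long axis -- is assigned to the slicing (z) axis; the
#' intermediate axis goes to x and the shortest to y. Applying the returned
#' rotation to the foreground coordinates about their centroid aligns the
#' long axis with z.
#'
#' Determinism: eigenvalue ties are resolved by matching eigenvectors to
#' the coordinate axes they are closest to (so cubes and axis-aligned boxes
#' return the identity); eigenvector signs are fixed by requiring a
#' non-negative projection on the slicing axis (ties fall through to x,
#' then y); the final axis is recomputed as a cross product so the result
#' is always a proper rotation (det = +1).
#'
#' @param mask A non-empty [segment_mask()].
#' @return List with `rotation` (3x3 orthonormal, det +1; rows are the
#'   target axes so aligned coordinates are `rotation %*% (p - center)`),
#'   `extents_mm` (sorted decreasing principal standard extents),
#'   `center` (foreground centroid, mm).
#' @export
inertia_axes_3d <- function(mask) {
  stopifnot(inherits(mask, "segment_mask"))
  xyz <- .foreground_coords_mm(mask)
  ctr <- colMeans(xyz)
  cov3 <- crossprod(sweep(xyz, 2, ctr)) / nrow(xyz)
  eg <- eigen(cov3, symmetric = TRUE)  # values decreasing
  vals <- eg$values
  vecs <- eg$vectors
  # target slots by extent: largest -> z (slot 3), middle -> x, smallest -> y
  slot <- c(3L, 1L, 2L)
  # resolve (near-)degenerate eigenvalue groups by snapping to nearest
  # coordinate axes, greedily by |dot|
  tol <- 1e-6 * max(vals, .Machine$double.eps)
  grp <- cumsum(c(TRUE, diff(vals) < -tol))
  for (g in unique(grp)) {
    members <- which(grp == g)
    if (length(members) < 2L) next
    slots_g <- slot[members]
    taken <- logical(3)
    for (m in members) {
      scores <- abs(vecs[, m])
      scores[!(seq_len(3) %in% slots_g) | taken] <- -Inf
      best <- which.max(scores)
      slot[m] <- best
      taken[best] <- TRUE
    }
  }
  V <- matrix(0, 3, 3)
  for (m in 1:3) V[, slot[m]] <- vecs[, m]
  # sign convention: non-negative projection on z, then x, then y
  fix_sign <- function(v) {
    for (ax in c(3L, 1L, 2L)) {
      if (abs(v[ax]) > 1e-12) return(if (v[ax] < 0) -v else v)
    }
    v
  }
  V[, 3] <- fix_sign(V[, 3])
  V[, 1] <- fix_sign(V[, 1])
  V[, 2] <- c(V[2, 3] * V[3, 1] - V[3, 3] * V[2, 1],   # z cross x
              V[3, 3] * V[1, 1] - V[1, 3] * V[3, 1],
              V[1, 3] * V[2, 1] - V[2, 3] * V[1, 1])
  rotation <- t(V)
  list(rotation = rotation,
       extents_mm = sqrt(pmax(vals, 0)),
       center = ctr)
}

.trilinear_sample <- function(arr, x, y, z) {
  d <- dim(arr)
  x0 <- pmin(pmax(floor(x), 1L), d[1] - 1L); x1 <- x0 + 1L
  y0 <- pmin(pmax(floor(y), 1L), d[2] - 1L); y1 <- y0 + 1L
  z0 <- pmin(pmax(floor(z), 1L), d[3] - 1L); z1 <- z0 + 1L
  fx <- pmin(pmax(x - x0, 0), 1)
  fy <- pmin(pmax(y - y0, 0), 1)
  fz <- pmin(pmax(z - z0, 0), 1)
  at <- function(i, j, k) arr[cbind(i, j, k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy       * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
  fz       * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
              fy       * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

#' Rotate a segment mask (and optional intensity volume)
#'
#' Resamples the mask on a new axis-aligned grid after rotation about the
#' given center. The mask uses nearest-neighbor interpolation (labels stay
#' binary); an intensity volume on the same grid is rotated with the same
#' transform using trilinear interpolation. The output grid is expanded so
#' no foreground voxel is clipped; spacing is preserved. Euler rotations
#' are applied in the fixed order x, then y, then z.
#'
#' @param mask A non-empty [segment_mask()].
#' @param spec A [rotation_spec()].
#' @param intensity Optional [voxel_volume()] on the same grid as `mask`.
#' @return A [segment_mask()]; when `intensity` is supplied, a list with
#'   elements `mask` and `intensity`.
#' @export
apply_rotation <- function(mask, spec, intensity = NULL) {
  stopifnot(inherits(mask, "segment_mask"), inherits(spec, "rotation_spec"))
  if (sum(mask$voxels) == 0L) stop("segment mask is empty", call. = FALSE)
  if (!is.null(intensity) &&
      !identical(dim(intensity$values), dim(mask$voxels)))
    stop("intensity volume and mask are on different grids", call. = FALSE)
  if (spec$mode == "none")
    return(if (is.null(intensity)) mask else
           list(mask = mask, intensity = intensity))
  M <- if (spec$mode == "principal_inertia") {
    inertia_axes_3d(mask)$rotation
  } else {
    a <- spec$euler_angles_deg * pi / 180
    .rot_z(a[3]) %*% .rot_y(a[2]) %*% .rot_x(a[1])
  }
  sp <- mask$spacing
  ctr <- if (is.null(spec$center)) colMeans(.foreground_coords_mm(mask)) else
    as.numeric(spec$center)

  # rotated foreground bounding box (corners of the occupied bbox, mm)
  idx <- which(mask$voxels != 0L, arr.ind = TRUE)
  lo <- (apply(idx, 2, min) - 1) * sp
  hi <- apply(idx, 2, max) * sp
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  rot_corners <- t(M %*% (t(corners) - ctr) + ctr)
  w_min <- apply(rot_corners, 2, min) - 2 * sp
  w_max <- apply(rot_corners, 2, max) + 2 * sp
  # phase-align the output lattice with the image of one input voxel center,
  # so lattice-preserving rotations (e.g. 90 deg) resample exactly
  t0 <- as.numeric(M %*% ((idx[1, ] - 0.5) * sp - ctr) + ctr)
  i0 <- round((t0 - w_min) / sp + 0.5)
  origin <- t0 - (i0 - 0.5) * sp
  n_out <- pmax(ceiling((w_max - origin) / sp), 1)

  ci <- origin[1] + (seq_len(n_out[1]) - 0.5) * sp[1]
  cj <- origin[2] + (seq_len(n_out[2]) - 0.5) * sp[2]
  ck <- origin[3] + (seq_len(n_out[3]) - 0.5) * sp[3]
  px <- rep(ci, times = n_out[2] * n_out[3]) - ctr[1]
  py <- rep(rep(cj, each = n_out[1]), times = n_out[3]) - ctr[2]
  pz <- rep(ck, each = n_out[1] * n_out[2]) - ctr[3]
  # inverse map: source = M^T (p - ctr) + ctr
  sx <- M[1, 1] * px + M[2, 1] * py + M[3, 1] * pz + ctr[1]
  sy <- M[1, 2] * px + M[2, 2] * py + M[3, 2] * pz + ctr[2]
  sz <- M[1, 3] * px + M[2, 3] * py + M[3, 3] * pz + ctr[3]
  fi <- sx / sp[1] + 0.5
  fj <- sy / sp[2] + 0.5
  fk <- sz / sp[3] + 0.5
  ii <- as.integer(round(fi)); jj <- as.integer(round(fj))
  kk <- as.integer(round(fk))
  d <- dim(mask$voxels)
  inside <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] &
    kk >= 1L & kk <= d[3]
  out <- integer(length(ii))
  out[inside] <- mask$voxels[cbind(ii[inside], jj[inside], kk[inside])]
  new_mask <- segment_mask(array(out, dim = n_out), spacing = sp,
                           label_value = mask$label_value)
  if (is.null(intensity)) return(new_mask)
  vals <- numeric(length(ii))
  vals[inside] <- .trilinear_sample(intensity$values, fi[inside], fj[inside],
                                    fk[inside])
  list(mask = new_mask,
       intensity = voxel_volume(array(vals, dim = n_out), spacing = sp))
}

.axis_id <- function(axis) {
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  axis <- as.integer(axis)
  if (is.na(axis) || axis < 1L || axis > 3L)
    stop("slicing axis must be 'x', 'y', 'z' or 1:3", call. = FALSE)
  axis
}

#' Slice a segment into cross-sections
#'
#' Iterates plane-by-plane along the chosen grid axis, between the first
#' and last plane containing foreground (inclusive). Planes with no
#' foreground inside that range are emitted as empty sections (flagged) so
#' slice indexing stays aligned with the volume. Percent-length of plane i
#' is `100 * (i - i_first) / (i_last - i_first)`; a single-plane structure
#' is at 0%.
#'
#' @param mask A non-empty [segment_mask()].
#' @param intensity Optional [voxel_volume()] on the same grid.
#' @param axis Slicing axis: `"x"`, `"y"`, `"z"` (default) or 1:3.
#' @return List of [slice_section()] objects in plane order.
#' @export
slice_stack <- function(mask, intensity = NULL, axis = "z") {
  stopifnot(inherits(mask, "segment_mask"))
  ax <- .axis_id(axis)
  if (!is.null(intensity) &&
      !identical(dim(intensity$values), dim(mask$voxels)))
    stop("intensity volume and mask are on different grids", call. = FALSE)
  counts <- apply(mask$voxels, ax, sum)
  occ <- which(counts > 0L)
  if (length(occ) == 0L) stop("segment mask is empty", call. = FALSE)
  i_first <- occ[1]; i_last <- occ[length(occ)]
  in_plane <- setdiff(1:3, ax)
  sp2 <- mask$spacing[in_plane]
  d3 <- dim(mask$voxels)
  take_plane <- function(arr, k) {
    switch(ax,
           array(arr[k, , ], dim = d3[2:3]),
           array(arr[, k, ], dim = d3[c(1, 3)]),
           array(arr[, , k], dim = d3[1:2]))
  }
  lapply(i_first:i_last, function(k) {
    pct <- if (i_last == i_first) 0 else
      100 * (k - i_first) / (i_last - i_first)
    slice_section(pixels = take_plane(mask$voxels, k),
                  pixel_spacing = sp2,
                  intensity = if (is.null(intensity)) NULL else
                    take_plane(intensity$values, k),
                  plane_index = k, percent_length = pct)
  })
}
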