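#' Construct a 2D cross-section
#'
#' A `slice_section` is one binary cross-section of a sliced structure: a
#' 2D pixel grid in which foreground pixels are material, with physical
#' pixel spacing in mm. The first grid axis is the slice's horizontal (+x)
#' axis and the second is vertical (+y, pointing up); angles are measured
#' in degrees counterclockwise from horizontal.
#'
#' @param pixels 2D binary matrix (nonzero = foreground).
#' @param pixel_spacing Numeric length-2 `(px, py)` in mm, both positive.
#' @param intensity Optional 2D scalar matrix with the same shape.
#' @param plane_index Integer plane index in the source volume.
#' @param percent_length Position along the structure, 0-100.
#' @return An object of class `slice_section`.
#' @export
slice_section <- function(pixels, pixel_spacing = c(1, 1), intensity = NULL,
                          plane_index = 1L, percent_length = 0) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  pixels[pixels != 0L] <- 1L
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0) ||
      any(!is.finite(pixel_spacing)))
    stop("`pixel_spacing` must be two positive finite numbers (mm)",
         call. = FALSE)
  if (!is.null(intensity)) {
    intensity <- as.matrix(intensity)
    if (!identical(dim(intensity), dim(pixels)))
      stop("`intensity` must have the same shape as `pixels`", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 intensity = intensity, plane_index = as.integer(plane_index),
                 percent_length = as.numeric(percent_length)),
            class = "slice_section")
}

#' @export
print.slice_section <- function(x, ...) {
  cat("<slice_section> plane ", x$plane_index, " (",
      signif(x$percent_length, 4), "% length); ",
      paste(dim(x$pixels), collapse = " x "), " px; ",
      sum(x$pixels), " foreground; spacing (mm): ",
      paste(signif(x$pixel_spacing, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.section_nonempty <- function(section) {
  if (sum(section$pixels) == 0L)
    stop("empty cross-section: no foreground pixels", call. = FALSE)
}

# foreground pixel-center coordinates in mm, columns x, y
.pixel_centers <- function(section) {
  idx <- which(section$pixels != 0L, arr.ind = TRUE)
  cbind(x = (idx[, 1] - 0.5) * section$pixel_spacing[1],
        y = (idx[, 2] - 0.5) * section$pixel_spacing[2])
}

#' Centroidal second-moment (inertia) tensor of a cross-section
#'
#' Each foreground pixel is modelled as a solid px-by-py rectangle centred
#' on its lattice point. It contributes its own rectangle moment
#' (`px*py^3/12` to Ixx, `px^3*py/12` to Iyy, 0 to Ixy) plus the
#' parallel-axis term `A_k * D_k^2`, where `A_k = px*py` and `D_k` is the
#' centroid-to-pixel-centre offset. Ixx is the second moment about the
#' horizontal centroidal axis, Iyy about the vertical, Ixy the product
#' moment.
#'
#' @param section A non-empty [slice_section()].
#' @return An object of class `inertia_tensor_2d`: `Ixx`, `Iyy`, `Ixy`
#'   (mm^4), `centroid` (mm), `area` (mm^2, CSA), and the per-pixel
#'   rectangle terms `own_xx`, `own_yy` (mm^4) retained for axis rotation.
#' @export
inertia_tensor <- function(section) {
  .section_nonempty(section)
  p <- section$pixel_spacing
  xy <- .pixel_centers(section)
  n <- nrow(xy)
  A_k <- p[1] * p[2]
  ctr <- colMeans(xy)
  dx <- xy[, 1] - ctr[1]
  dy <- xy[, 2] - ctr[2]
  own_xx <- n * p[1] * p[2]^3 / 12
  own_yy <- n * p[1]^3 * p[2] / 12
  structure(list(Ixx = own_xx + A_k * sum(dy^2),
                 Iyy = own_yy + A_k * sum(dx^2),
                 Ixy = A_k * sum(dx * dy),
                 centroid = ctr,
                 area = n * A_k,
                 own_xx = own_xx, own_yy = own_yy),
            class = "inertia_tensor_2d")
}

#' Second moment of area about a centroidal axis at an angle
#'
#' Rotates the centroidal tensor to the axis at `angle_deg` degrees
#' counterclockwise from horizontal:
#' `I(theta) = Ixx cos^2 + Iyy sin^2 - 2 Ixy sin cos`
#' for the parallel-axis part, plus the per-pixel rectangle moments rotated
#' with the same formula. Identical (to rounding) to re-summing every
#' pixel's contribution about the tilted axis directly.
#'
#' @param tensor An [inertia_tensor()] result.
#' @param angle_deg Neutral-axis angle in degrees from horizontal.
#' @return Second moment of area in mm^4.
#' @export
second_moment_about_axis <- function(tensor, angle_deg) {
  stopifnot(inherits(tensor, "inertia_tensor_2d"))
  th <- angle_deg * pi / 180
  c2 <- cos(th)^2; s2 <- sin(th)^2; sc <- sin(th) * cos(th)
  pa_xx <- tensor$Ixx - tensor$own_xx
  pa_yy <- tensor$Iyy - tensor$own_yy
  (pa_xx * c2 + pa_yy * s2 - 2 * tensor$Ixy * sc) +
    (tensor$own_xx * c2 + tensor$own_yy * s2)
}

#' Principal axes of a cross-section
#'
#' The principal axes are the perpendicular centroidal axes about which the
#' product moment of inertia is zero; they carry the extreme values of I.
#' Following the biomechanics convention, I about the minor principal axis
#' is the maximum (highest bending resistance) and I about the major
#' principal axis is the minimum. `theta_principal` is the angle of the
#' major axis (minimum I), in degrees counterclockwise from horizontal,
#' mapped into (-90, 90]; isotropic tensors (circle-like) return 0 by
#' tie-break.
#'
#' @param tensor An [inertia_tensor()] result.
#' @return List with `theta_principal` (degrees), `I_about_minor_axis`
#'   and `I_about_major_axis` (mm^4).
#' @export
principal_axes <- function(tensor) {
  stopifnot(inherits(tensor, "inertia_tensor_2d"))
  Ixx <- tensor$Ixx; Iyy <- tensor$Iyy; Ixy <- tensor$Ixy
  mean_I <- (Ixx + Iyy) / 2
  R <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  I_max <- mean_I + R
  I_min <- mean_I - R
  J <- Ixx + Iyy
  if (abs(Ixx - Iyy) <= 1e-12 * J && abs(Ixy) <= 1e-12 * J) {
    theta <- 0
  } else {
    # minimising direction of I(theta) = [c,s] M [c,s]^T, M = [[Ixx,-Ixy],[-Ixy,Iyy]]
    eg <- eigen(matrix(c(Ixx, -Ixy, -Ixy, Iyy), 2, 2), symmetric = TRUE)
    v <- eg$vectors[, 2]  # smallest eigenvalue
    theta <- atan2(v[2], v[1]) * 180 / pi
    if (theta <= -90) theta <- theta + 180
    if (theta > 90) theta <- theta - 180
    if (abs(theta + 90) < 1e-9) theta <- 90
  }
  list(theta_principal = theta,
       I_about_minor_axis = I_max,
       I_about_major_axis = I_min)
}

# max perpendicular pixel-centre distance to the centroidal axis at angle
.max_axis_distance <- function(section, tensor, angle_deg) {
  th <- angle_deg * pi / 180
  xy <- .pixel_centers(section)
  max(abs(-(xy[, 1] - tensor$centroid[1]) * sin(th) +
           (xy[, 2] - tensor$centroid[2]) * cos(th)))
}

#' Section modulus about a centroidal axis
#'
#' `Z = I(theta) / c`, where `c` is the largest perpendicular distance from
#' the axis to a foreground pixel centre. Proportional to the bending
#' strength of the section: the farthest pixel is where bending failure
#' starts.
#'
#' @param section A non-empty [slice_section()].
#' @param tensor The section's [inertia_tensor()] (computed when omitted).
#' @param angle_deg Neutral-axis angle in degrees from horizontal.
#' @return Section modulus in mm^3, or `NA` (flagged with a warning) for
#'   degenerate sections lying entirely on the axis (c = 0).
#' @export
section_modulus <- function(section, tensor = NULL, angle_deg = 0) {
  .section_nonempty(section)
  if (is.null(tensor)) tensor <- inertia_tensor(section)
  cmax <- .max_axis_distance(section, tensor, angle_deg)
  if (cmax <= 0) {
    warning("degenerate section: all pixel centres lie on the neutral axis; ",
            "section modulus undefined")
    return(NA_real_)
  }
  second_moment_about_axis(tensor, angle_deg) / cmax
}

#' Polar moment of inertia
#'
#' The sum over pixels of squared centroid distance times pixel area; by
#' the perpendicular-axis identity this equals `Ixx + Iyy` exactly under
#' the same per-pixel model. Quantifies shape-based torsion resistance.
#'
#' @param tensor An [inertia_tensor()] result.
#' @return J in mm^4.
#' @export
polar_moment <- function(tensor) {
  stopifnot(inherits(tensor, "inertia_tensor_2d"))
  tensor$Ixx + tensor$Iyy
}

#' Maximum Feret diameter
#'
#' Greatest caliper distance across the section: the maximum pairwise
#' distance between corner points of foreground pixels, computed on the
#' convex hull of the boundary-pixel corners. A single pixel therefore has
#' Feret diameter equal to its corner-to-corner diagonal.
#'
#' @param section A non-empty [slice_section()].
#' @return Maximum Feret diameter in mm.
#' @export
feret_max <- function(section) {
  .section_nonempty(section)
  p <- section$pixel_spacing
  m <- section$pixels
  d <- dim(m)
  # boundary pixels: foreground with at least one 4-neighbour background
  pad <- matrix(0L, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)] &
    pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  idx <- which(m == 1L & !core, arr.ind = TRUE)
  xs <- c((idx[, 1] - 1) * p[1], (idx[, 1] - 1) * p[1],
          idx[, 1] * p[1], idx[, 1] * p[1])
  ys <- c((idx[, 2] - 1) * p[2], idx[, 2] * p[2],
          (idx[, 2] - 1) * p[2], idx[, 2] * p[2])
  hull <- grDevices::chull(xs, ys)
  hx <- xs[hull]; hy <- ys[hull]
  if (length(hull) == 1L) return(0)
  max(stats::dist(cbind(hx, hy)))
}

# marching-squares isocontour length of a scalar field sampled at pixel
# centres, with linear interpolation of the 0.5-level crossings on cell
# edges. Saddle cells are split into the two-segment resolution (both
# choices have very similar total length, so the estimator is insensitive
# to the tie-break).
.contour_length <- function(field, px, py, level = 0.5) {
  d <- dim(field)
  nr <- d[1] - 1L; nc <- d[2] - 1L
  a <- field[1:nr, 1:nc]                      # corner (i,   j)
  b <- field[2:(nr + 1L), 1:nc]               # corner (i+1, j)
  cc <- field[1:nr, 2:(nc + 1L)]              # corner (i,   j+1)
  dd <- field[2:(nr + 1L), 2:(nc + 1L)]       # corner (i+1, j+1)
  config <- (a > level) + 2L * (b > level) + 4L * (cc > level) +
    8L * (dd > level)
  frac <- function(v0, v1) (level - v0) / (v1 - v0)
  # crossing coordinates in cell-local mm; edge names by location
  bot_x <- frac(a, b) * px    # on edge a-b, y = 0
  top_x <- frac(cc, dd) * px  # on edge cc-dd, y = py
  lef_y <- frac(a, cc) * py   # on edge a-cc, x = 0
  rig_y <- frac(b, dd) * py   # on edge b-dd, x = px
  seg <- function(x0, y0, x1, y1) sqrt((x1 - x0)^2 + (y1 - y0)^2)
  len <- numeric(length(config))
  pick <- function(cfg) config == cfg
  add <- function(cfgs, x0, y0, x1, y1) {
    for (cfg in cfgs) {
      w <- pick(cfg)
      len[w] <<- len[w] + seg(x0[w], y0[w], x1[w], y1[w])
    }
  }
  zero <- array(0, dim(a)); pxm <- array(px, dim(a)); pym <- array(py, dim(a))
  add(c(1, 14), zero, lef_y, bot_x, zero)      # left-bottom
  add(c(2, 13), bot_x, zero, pxm, rig_y)       # bottom-right
  add(c(3, 12), zero, lef_y, pxm, rig_y)       # left-right
  add(c(4, 11), zero, lef_y, top_x, pym)       # left-top
  add(c(5, 10), bot_x, zero, top_x, pym)       # bottom-top
  add(c(7, 8), pxm, rig_y, top_x, pym)         # right-top
  add(c(6, 9), zero, lef_y, bot_x, zero)       # saddles: two segments
  add(c(6, 9), pxm, rig_y, top_x, pym)
  sum(len)
}

#' Perimeter of a cross-section
#'
#' Total length of the sub-pixel 0.5-level isocontour of the pixel field
#' (marching squares with linearly interpolated edge crossings), summed
#' over all boundaries, outer and inner. To place crossings at sub-pixel
#' positions the binary field is first smoothed with a 3x3 mean filter;
#' this removes the staircase bias of midpoint crossings on binary data.
#' Features thinner than about 2 pixels vanish under the smoothing, so
#' sections whose smoothed field never reaches 0.5 fall back to the
#' unsmoothed binary contour. Supports anisotropic pixels.
#'
#' @param section A non-empty [slice_section()].
#' @return Perimeter in mm.
#' @export
perimeter <- function(section) {
  .section_nonempty(section)
  p <- section$pixel_spacing
  m <- section$pixels
  d <- dim(m)
  pad <- matrix(0, d[1] + 4L, d[2] + 4L)
  pad[3:(d[1] + 2L), 3:(d[2] + 2L)] <- m
  # 3x3 mean filter via shifted sums
  n1 <- nrow(pad); n2 <- ncol(pad)
  sm <- matrix(0, n1 - 2L, n2 - 2L)
  for (di in 0:2) for (dj in 0:2)
    sm <- sm + pad[(1L + di):(n1 - 2L + di), (1L + dj):(n2 - 2L + dj)]
  sm <- sm / 9
  if (any(sm > 0.5)) return(.contour_length(sm, p[1], p[2]))
  # sub-resolution fallback: contour the binary field directly
  .contour_length(pad[2:(n1 - 1L), 2:(n2 - 1L)], p[1], p[2])
}

#' Mean brightness over the foreground
#'
#' Arithmetic mean of the intensity values over foreground pixels only;
#' background is excluded. Returns `NA` when the section carries no
#' intensity grid.
#'
#' @param section A [slice_section()] with an `intensity` grid.
#' @return Mean intensity (arbitrary units) or `NA`.
#' @export
mean_brightness <- function(section) {
  .section_nonempty(section)
  if (is.null(section$intensity)) return(NA_real_)
  mean(section$intensity[section$pixels == 1L])
}

#' Total cross-sectional area including vacuities
#'
#' Area of the foreground plus all enclosed background regions (background
#' components not connected to the slice border under 4-connectivity;
#' foreground connectivity is 8). A notch open to the border is not a
#' vacuity.
#'
#' @param section A non-empty [slice_section()].
#' @return TCSA in mm^2; always >= the foreground CSA.
#' @export
total_area_with_vacuities <- function(section) {
  .section_nonempty(section)
  filled <- EBImage::fillHull(section$pixels)
  sum(filled != 0) * prod(section$pixel_spacing)
}

#' Compactness of a cross-section
#'
#' `CSA / TCSA`: the material area divided by the total area enclosed by
#' the outer boundary (material plus internal vacuities). 1 for a solid
#' section; lower for hollow ones.
#'
#' @param CSA Cross-sectional material area, mm^2.
#' @param TCSA Total area including vacuities, mm^2 (> 0).
#' @return Dimensionless ratio in (0, 1].
#' @export
compactness <- function(CSA, TCSA) {
  if (!is.finite(TCSA) || TCSA <= 0)
    stop("TCSA must be positive", call. = FALSE)
  CSA / TCSA
}

# restrict a section to its largest 8-connected foreground component
.largest_island <- function(section) {
  lab <- EBImage::bwlabel(section$pixels)
  if (max(lab) <= 1) return(section)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  section$pixels <- (lab == keep) * 1L
  storage.mode(section$pixels) <- "integer"
  section
}

#' All cross-sectional properties of one slice
#'
#' Computes the full per-slice record: CSA, centroid, the centroidal
#' inertia tensor, principal axes and principal second moments, second
#' moment and section modulus about an optional user neutral axis, section
#' moduli about both principal axes, polar moment, maximum Feret diameter,
#' perimeter, mean brightness, total area with vacuities and compactness.
#' An empty section yields a record of `NA`s with `empty = TRUE`.
#'
#' @param section A [slice_section()].
#' @param neutral_axis_deg Optional neutral-axis angle in degrees from
#'   horizontal (the axis passes through the centroid).
#' @param largest_island If `TRUE`, restrict to the largest connected
#'   foreground component before measuring.
#' @return A list of class `section_properties`.
#' @export
section_properties <- function(section, neutral_axis_deg = NULL,
                               largest_island = FALSE) {
  stopifnot(inherits(section, "slice_section"))
  empty_rec <- list(
    plane_index = section$plane_index,
    percent_length = section$percent_length,
    empty = TRUE, CSA = NA_real_, centroid_x = NA_real_,
    centroid_y = NA_real_, Ixx = NA_real_, Iyy = NA_real_, Ixy = NA_real_,
    theta_principal = NA_real_, I_about_minor_axis = NA_real_,
    I_about_major_axis = NA_real_, I_NA = NA_real_, Z_NA = NA_real_,
    Z_minor_axis = NA_real_, Z_major_axis = NA_real_, J = NA_real_,
    feret_max = NA_real_, perimeter = NA_real_, mean_brightness = NA_real_,
    TCSA = NA_real_, compactness = NA_real_)
  if (sum(section$pixels) == 0L)
    return(structure(empty_rec, class = "section_properties"))
  if (largest_island) section <- .largest_island(section)
  tensor <- inertia_tensor(section)
  pr <- principal_axes(tensor)
  tcsa <- total_area_with_vacuities(section)
  theta_minor <- pr$theta_principal + 90
  rec <- list(
    plane_index = section$plane_index,
    percent_length = section$percent_length,
    empty = FALSE,
    CSA = tensor$area,
    centroid_x = tensor$centroid[[1]], centroid_y = tensor$centroid[[2]],
    Ixx = tensor$Ixx, Iyy = tensor$Iyy, Ixy = tensor$Ixy,
    theta_principal = pr$theta_principal,
    I_about_minor_axis = pr$I_about_minor_axis,
    I_about_major_axis = pr$I_about_major_axis,
    I_NA = if (is.null(neutral_axis_deg)) NA_real_ else
      second_moment_about_axis(tensor, neutral_axis_deg),
    Z_NA = if (is.null(neutral_axis_deg)) NA_real_ else
      section_modulus(section, tensor, neutral_axis_deg),
    Z_minor_axis = section_modulus(section, tensor, theta_minor),
    Z_major_axis = section_modulus(section, tensor, pr$theta_principal),
    J = polar_moment(tensor),
    feret_max = feret_max(section),
    perimeter = perimeter(section),
    mean_brightness = mean_brightness(section),
    TCSA = tcsa,
    compactness = compactness(tensor$area, tcsa))
  structure(rec, class = "section_properties")
}
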