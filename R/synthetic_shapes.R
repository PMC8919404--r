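#' Specify a canonical beam shape
#'
#' Describes a rasterizable beam with known closed-form section properties,
#' used to validate the geometry engine without any external data. The
#' cross-section lies in the x-y plane and the beam is extruded along z
#' (except `oblique_cylinder`, whose axis is tilted in the x-z plane, and
#' `dumbbell`, which leaves a gap of empty planes mid-beam).
#'
#' Kind-specific dimensions (mm):
#' * `cylinder`: `r`
#' * `tube`: `ro`, `ri` (wall `ro - ri`)
#' * `box`: `w` (x extent), `h` (y extent)
#' * `elliptical_beam`: `a` (semi-axis along x), `b` (along y)
#' * `i_beam`: `w` (flange width), `h` (total height), `tf` (flange
#'   thickness), `tw` (web thickness)
#' * `oblique_cylinder`: `r`, `tilt_deg` (axis tilt from z, about y)
#' * `dumbbell`: `w`, `h` (box section), `gap_mm` (empty mid-span)
#'
#' @param kind Shape kind (see above).
#' @param dimensions Named list of dimensions in mm.
#' @param length Beam length along its axis, mm.
#' @param pitch Voxel pitch in mm: scalar (isotropic) or length 3.
#' @param intensity_fill `NULL`, a constant, or `"gradient"` (linear in y)
#'   for brightness tests.
#' @param rotate_deg Optional in-plane rotation of the cross-section,
#'   degrees counterclockwise (prismatic kinds only).
#' @param seed Integer recorded for provenance; rasterization is
#'   deterministic.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("cylinder", "tube", "box", "elliptical_beam",
                                "i_beam", "oblique_cylinder", "dumbbell"),
                       dimensions, length = 10, pitch = 0.2,
                       intensity_fill = NULL, rotate_deg = 0, seed = 1L) {
  kind <- match.arg(kind)
  dims <- as.list(dimensions)
  need <- switch(kind,
                 cylinder = "r", tube = c("ro", "ri"), box = c("w", "h"),
                 elliptical_beam = c("a", "b"),
                 i_beam = c("w", "h", "tf", "tw"),
                 oblique_cylinder = c("r", "tilt_deg"),
                 dumbbell = c("w", "h", "gap_mm"))
  missing <- setdiff(need, names(dims))
  if (length(missing) > 0L)
    stop(kind, " requires dimension(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sizes <- unlist(dims[setdiff(need, "tilt_deg")])
  if (any(sizes <= 0))
    stop("all dimensions must be positive", call. = FALSE)
  if (kind == "tube" && dims$ri >= dims$ro)
    stop("tube requires ri < ro", call. = FALSE)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3)
  if (any(pitch <= 0)) stop("pitch must be positive", call. = FALSE)
  structure(list(kind = kind, dimensions = dims, length = length,
                 pitch = as.numeric(pitch), intensity_fill = intensity_fill,
                 rotate_deg = rotate_deg, seed = as.integer(seed)),
            class = "shape_spec")
}

# inside test for the cross-section at centered in-plane coords (mm);
# returns logical vector
.inside_section <- function(spec, x, y) {
  if (spec$rotate_deg != 0) {
    th <- -spec$rotate_deg * pi / 180  # rotate sampling points backwards
    xr <- x * cos(th) - y * sin(th)
    yr <- x * sin(th) + y * cos(th)
    x <- xr; y <- yr
  }
  d <- spec$dimensions
  switch(spec$kind,
         cylinder = x^2 + y^2 <= d$r^2,
         oblique_cylinder = x^2 + y^2 <= d$r^2,
         tube = {
           r2 <- x^2 + y^2
           r2 <= d$ro^2 & r2 > d$ri^2
         },
         box = abs(x) <= d$w / 2 & abs(y) <= d$h / 2,
         dumbbell = abs(x) <= d$w / 2 & abs(y) <= d$h / 2,
         elliptical_beam = (x / d$a)^2 + (y / d$b)^2 <= 1,
         i_beam = {
           in_outer <- abs(x) <= d$w / 2 & abs(y) <= d$h / 2
           in_notch <- abs(x) > d$tw / 2 & abs(y) < d$h / 2 - d$tf
           in_outer & !in_notch
         })
}

.section_bbox <- function(spec) {
  d <- spec$dimensions
  half <- switch(spec$kind,
                 cylinder = c(d$r, d$r),
                 oblique_cylinder = c(d$r, d$r),
                 tube = c(d$ro, d$ro),
                 box = c(d$w, d$h) / 2,
                 dumbbell = c(d$w, d$h) / 2,
                 elliptical_beam = c(d$a, d$b),
                 i_beam = c(d$w, d$h) / 2)
  if (spec$rotate_deg != 0) half <- rep(sqrt(sum(half^2)), 2)
  half
}

#' Rasterize a single cross-section of a shape
#'
#' Pixel centres inside the continuous section are foreground (no
#' anti-aliasing or partial volume), matching the binary pixel model of
#' the geometry engine. Useful for validating per-slice metrics at fine
#' pitch without building a full 3D stack.
#'
#' @param spec A [shape_spec()] (prismatic kinds).
#' @return A [slice_section()]; intensity attached per
#'   `spec$intensity_fill`.
#' @export
rasterize_section <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  p <- spec$pitch[1:2]
  half <- .section_bbox(spec) + 2 * p
  n <- pmax(ceiling(2 * half / p), 3)
  cx <- (seq_len(n[1]) - (n[1] + 1) / 2) * p[1]
  cy <- (seq_len(n[2]) - (n[2] + 1) / 2) * p[2]
  xg <- rep(cx, times = n[2])
  yg <- rep(cy, each = n[1])
  m <- matrix(as.integer(.inside_section(spec, xg, yg)), n[1], n[2])
  intens <- .fill_intensity(spec, xg, yg, n)
  slice_section(m, pixel_spacing = p, intensity = intens)
}

.fill_intensity <- function(spec, xg, yg, n) {
  f <- spec$intensity_fill
  if (is.null(f)) return(NULL)
  if (identical(f, "gradient")) return(matrix(100 + yg, n[1], n[2]))
  matrix(as.numeric(f), n[1], n[2])
}

#' Rasterize a shape into a 3D segment mask
#'
#' Voxel centres inside the continuous solid are foreground. One empty
#' margin plane is added at each end (and one empty voxel in-plane) so the
#' shape never touches the grid border. Ground truth from
#' [closed_form_properties()] is attached as the `ground_truth` attribute.
#'
#' @param spec A [shape_spec()].
#' @param max_voxels Guard against accidental huge grids; exceeding it is
#'   an error suggesting a coarser pitch.
#' @return A [segment_mask()]; when `spec$intensity_fill` is set, a list
#'   with elements `mask` and `intensity`.
#' @export
rasterize <- function(spec, max_voxels = 2e8) {
  stopifnot(inherits(spec, "shape_spec"))
  p <- spec$pitch
  half <- .section_bbox(spec)
  if (spec$kind == "oblique_cylinder") {
    th <- spec$dimensions$tilt_deg * pi / 180
    half[1] <- (spec$length / 2) * abs(sin(th)) +
      spec$dimensions$r * abs(cos(th))
    hz <- (spec$length / 2) * abs(cos(th)) + spec$dimensions$r * abs(sin(th))
  } else {
    hz <- spec$length / 2
  }
  half <- half + 2 * p[1:2]
  hz <- hz + 2 * p[3]
  n <- pmax(ceiling(c(2 * half, 2 * hz) / p), 3)
  if (prod(n) > max_voxels)
    stop("rasterized grid would need ", prod(n), " voxels (> ", max_voxels,
         "); use a coarser pitch", call. = FALSE)
  cx <- (seq_len(n[1]) - (n[1] + 1) / 2) * p[1]
  cy <- (seq_len(n[2]) - (n[2] + 1) / 2) * p[2]
  cz <- (seq_len(n[3]) - (n[3] + 1) / 2) * p[3]

  if (spec$kind == "oblique_cylinder") {
    th <- spec$dimensions$tilt_deg * pi / 180
    u <- c(sin(th), 0, cos(th))
    xg <- rep(cx, times = n[2] * n[3])
    yg <- rep(rep(cy, each = n[1]), times = n[3])
    zg <- rep(cz, each = n[1] * n[2])
    t_ax <- xg * u[1] + zg * u[3]
    rad2 <- (xg - t_ax * u[1])^2 + yg^2 + (zg - t_ax * u[3])^2
    vox <- as.integer(rad2 <= spec$dimensions$r^2 &
                        abs(t_ax) <= spec$length / 2)
    mask <- segment_mask(array(vox, dim = n), spacing = p)
  } else {
    xg <- rep(cx, times = n[2])
    yg <- rep(cy, each = n[1])
    sec <- matrix(as.integer(.inside_section(spec, xg, yg)), n[1], n[2])
    along <- abs(cz) <= spec$length / 2
    if (spec$kind == "dumbbell") {
      along <- along & abs(cz) > spec$dimensions$gap_mm / 2
    }
    vox <- array(0L, dim = n)
    vox[, , along] <- sec
    mask <- segment_mask(vox, spacing = p)
  }
  attr(mask, "ground_truth") <- tryCatch(closed_form_properties(spec),
                                         error = function(e) NULL)
  if (is.null(spec$intensity_fill)) return(mask)
  xg2 <- rep(cx, times = n[2])
  yg2 <- rep(cy, each = n[1])
  plane <- .fill_intensity(spec, xg2, yg2, n)
  intens <- voxel_volume(array(rep(plane, n[3]), dim = n), spacing = p)
  list(mask = mask, intensity = intens)
}

# Ramanujan II approximation to the ellipse perimeter
.ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Closed-form section properties of a canonical shape
#'
#' Continuum ground truth for the rasterized fixtures: CSA, Ixx/Iyy about
#' the horizontal/vertical centroidal axes (before any in-plane rotation),
#' principal second moments, section modulus about the horizontal axis, J,
#' perimeter, maximum Feret diameter and compactness. The I-beam values
#' come from composite-rectangle summation (outer rectangle minus the two
#' notch rectangles), which independently exercises the additivity of the
#' per-pixel summation.
#'
#' @param spec A [shape_spec()] with a closed-form kind (`dumbbell`
#'   interior slices have none).
#' @return Named list of ground-truth values (mm-based units), including
#'   `tilt_deg` for `oblique_cylinder`.
#' @export
closed_form_properties <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  d <- spec$dimensions
  out <- switch(spec$kind,
    cylinder = ,
    oblique_cylinder = {
      r <- d$r
      list(CSA = pi * r^2, Ixx = pi * r^4 / 4, Iyy = pi * r^4 / 4,
           Z = pi * r^3 / 4, J = pi * r^4 / 2, perimeter = 2 * pi * r,
           feret = 2 * r, compactness = 1)
    },
    tube = {
      ro <- d$ro; ri <- d$ri
      I <- pi * (ro^4 - ri^4) / 4
      list(CSA = pi * (ro^2 - ri^2), Ixx = I, Iyy = I, Z = I / ro,
           J = 2 * I, perimeter = 2 * pi * (ro + ri), feret = 2 * ro,
           compactness = (ro^2 - ri^2) / ro^2)
    },
    box = {
      w <- d$w; h <- d$h
      list(CSA = w * h, Ixx = w * h^3 / 12, Iyy = h * w^3 / 12,
           Z = w * h^2 / 6, J = w * h^3 / 12 + h * w^3 / 12,
           perimeter = 2 * (w + h), feret = sqrt(w^2 + h^2),
           compactness = 1)
    },
    elliptical_beam = {
      a <- d$a; b <- d$b
      list(CSA = pi * a * b, Ixx = pi * a * b^3 / 4, Iyy = pi * a^3 * b / 4,
           Z = pi * a * b^2 / 4,
           J = pi * a * b^3 / 4 + pi * a^3 * b / 4,
           perimeter = .ellipse_perimeter(a, b),
           feret = 2 * max(a, b), compactness = 1)
    },
    i_beam = {
      w <- d$w; h <- d$h; tf <- d$tf; tw <- d$tw
      nw <- (w - tw) / 2         # notch width (each side)
      nh <- h - 2 * tf           # notch height
      Ixx <- w * h^3 / 12 - 2 * (nw * nh^3 / 12)  # notches centred on axis
      Iyy <- 2 * (tf * w^3 / 12) + nh * tw^3 / 12
      CSA <- w * h - 2 * nw * nh
      list(CSA = CSA, Ixx = Ixx, Iyy = Iyy, Z = Ixx / (h / 2),
           J = Ixx + Iyy, perimeter = 4 * w - 2 * tw + 2 * h,
           feret = sqrt(w^2 + h^2), compactness = 1)
    },
    stop("no closed form for kind '", spec$kind, "'", call. = FALSE))
  out$I_about_minor_axis <- max(out$Ixx, out$Iyy)
  out$I_about_major_axis <- min(out$Ixx, out$Iyy)
  out$length <- spec$length
  if (spec$kind == "oblique_cylinder") out$tilt_deg <- d$tilt_deg
  out
}
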