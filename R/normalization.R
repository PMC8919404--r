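#' Length-normalize a section property
#'
#' Reduces a section property to a dimensionless linear measure by taking
#' the root matching its dimensionality and dividing by the structure
#' length: CSA (mm^2) uses the square root, Z (mm^3) the cube root, I and
#' J (mm^4) the fourth root. Invariant under isometric rescaling of the
#' whole beam.
#'
#' @param value Non-negative property value (mm^k).
#' @param root_order 2, 3 or 4, matching the property's units.
#' @param L Structure length in mm (> 0).
#' @return `value^(1/root_order) / L`, dimensionless.
#' @export
length_normalize <- function(value, root_order, L) {
  if (!root_order %in% c(2, 3, 4))
    stop("root_order must be 2 (area), 3 (section modulus) or 4 (I, J)",
         call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("L must be positive", call. = FALSE)
  if (any(value < 0, na.rm = TRUE))
    stop("value must be non-negative", call. = FALSE)
  value^(1 / root_order) / L
}

# closed-form properties of the solid circle with area CSA (radius sqrt(CSA/pi))
.equal_area_circle <- function(CSA, kind) {
  switch(kind,
         I = CSA^2 / (4 * pi),
         J = CSA^2 / (2 * pi),
         Z = CSA^1.5 / (4 * sqrt(pi)),
         stop("kind must be 'I', 'Z' or 'J'", call. = FALSE))
}

#' Material-normalize a section property
#'
#' Divides I, Z or J by the same property of a solid circle with the same
#' cross-sectional area (radius `sqrt(CSA/pi)`), isolating the effect of
#' how the material is arranged: a ratio above 1 means the shape resists
#' bending (or torsion) better than a solid circular section of equal
#' material.
#'
#' @param value Property value (mm^4 for I and J, mm^3 for Z).
#' @param kind `"I"`, `"Z"` or `"J"`.
#' @param CSA Cross-sectional area in mm^2 (> 0).
#' @return Dimensionless ratio.
#' @export
material_normalize <- function(value, kind, CSA) {
  if (!is.finite(CSA) || CSA <= 0) stop("CSA must be positive", call. = FALSE)
  value / .equal_area_circle(CSA, kind)
}

#' Normalized properties of one slice
#'
#' Applies the length normalization (roots then division by length) and the
#' material normalization (ratio to the equal-area solid circle) to a
#' slice's raw properties. Normalizations use the second moment about the
#' minor and major principal axes and, when present, the user neutral
#' axis.
#'
#' @param props A [section_properties()] record.
#' @param L Structure length in mm.
#' @return A list of class `normalized_properties` (all dimensionless):
#'   length-normalized I (both principal and user axes), Z, J and CSA, and
#'   material-normalized I, Z and J.
#' @export
normalize_properties <- function(props, L) {
  stopifnot(inherits(props, "section_properties"))
  if (isTRUE(props$empty)) {
    nm <- c("I_minor_axis_lennorm", "I_major_axis_lennorm", "I_NA_lennorm",
            "Z_minor_axis_lennorm", "Z_major_axis_lennorm", "Z_NA_lennorm",
            "J_lennorm", "CSA_lennorm",
            "I_minor_axis_matnorm", "I_major_axis_matnorm", "I_NA_matnorm",
            "Z_minor_axis_matnorm", "Z_major_axis_matnorm", "Z_NA_matnorm",
            "J_matnorm")
    out <- as.list(rep(NA_real_, length(nm)))
    names(out) <- nm
    return(structure(out, class = "normalized_properties"))
  }
  ln <- function(v, k) if (is.na(v)) NA_real_ else length_normalize(v, k, L)
  mn <- function(v, kind) if (is.na(v)) NA_real_ else
    material_normalize(v, kind, props$CSA)
  structure(list(
    I_minor_axis_lennorm = ln(props$I_about_minor_axis, 4),
    I_major_axis_lennorm = ln(props$I_about_major_axis, 4),
    I_NA_lennorm = ln(props$I_NA, 4),
    Z_minor_axis_lennorm = ln(props$Z_minor_axis, 3),
    Z_major_axis_lennorm = ln(props$Z_major_axis, 3),
    Z_NA_lennorm = ln(props$Z_NA, 3),
    J_lennorm = ln(props$J, 4),
    CSA_lennorm = ln(props$CSA, 2),
    I_minor_axis_matnorm = mn(props$I_about_minor_axis, "I"),
    I_major_axis_matnorm = mn(props$I_about_major_axis, "I"),
    I_NA_matnorm = mn(props$I_NA, "I"),
    Z_minor_axis_matnorm = mn(props$Z_minor_axis, "Z"),
    Z_major_axis_matnorm = mn(props$Z_major_axis, "Z"),
    Z_NA_matnorm = mn(props$Z_NA, "Z"),
    J_matnorm = mn(props$J, "J")),
    class = "normalized_properties")
}
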