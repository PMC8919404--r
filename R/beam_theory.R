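#' Euler-Bernoulli beam deflection
#'
#' Small-deflection, no-shear deflection of a prismatic beam under a point
#' load: a cantilever loaded at its free end deflects
#' `delta = F L^3 / (3 E I)`; a simply supported beam loaded at midspan
#' deflects `delta = F L^3 / (48 E I)`. The small-deflection assumption is
#' flagged as satisfied when `delta < 0.10 * L`.
#'
#' @param F Load in N (>= 0).
#' @param L Beam length in mm (> 0).
#' @param E Elastic modulus in N/mm^2 (> 0).
#' @param I Second moment of area in mm^4 (> 0).
#' @param configuration `"cantilever_end_load"` or
#'   `"simply_supported_midpoint"`.
#' @return A list of class `deflection_case` with the inputs plus `delta`
#'   (mm) and `small_deflection_ok`.
#' @export
deflection <- function(F, L, E, I,
                       configuration = c("cantilever_end_load",
                                         "simply_supported_midpoint")) {
  configuration <- match.arg(configuration)
  if (!is.finite(F) || F < 0) stop("F must be >= 0", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("L must be positive", call. = FALSE)
  if (!is.finite(E) || E <= 0) stop("E must be positive", call. = FALSE)
  if (!is.finite(I) || I <= 0) stop("I must be positive", call. = FALSE)
  coef <- switch(configuration,
                 cantilever_end_load = 3,
                 simply_supported_midpoint = 48)
  delta <- F * L^3 / (coef * E * I)
  structure(list(F = F, L = L, E = E, I = I, configuration = configuration,
                 delta = delta, small_deflection_ok = delta < 0.10 * L),
            class = "deflection_case")
}

#' Beam-theory validity check for a sliced structure
#'
#' Euler-Bernoulli theory assumes a slender beam: shear contributes
#' negligibly when the length-to-width aspect ratio is at least 10. The
#' width is taken as the smallest per-slice maximum Feret diameter after
#' ignoring the first 5% of slices on each end (trim count
#' `floor(0.05 * n_occupied)` per end, so 0 for stacks under 20 occupied
#' slices), which guards the estimate against flared or ragged ends.
#' A warning is raised when the ratio falls below 10 (a ratio of exactly
#' 10 passes).
#'
#' @param sections List of [section_properties()] records.
#' @param L Structure length in mm.
#' @return A list of class `beam_report`: `length_L`, `min_max_feret`,
#'   `aspect_ratio`, `shear_warning`, `trim_fraction`.
#' @export
beam_check <- function(sections, L) {
  if (!is.finite(L) || L <= 0) stop("L must be positive", call. = FALSE)
  occupied <- Filter(function(s) !isTRUE(s$empty), sections)
  n_occ <- length(occupied)
  if (n_occ == 0L) stop("all sections are empty", call. = FALSE)
  trim <- floor(0.05 * n_occ)
  keep <- occupied[seq(trim + 1L, n_occ - trim)]
  ferets <- vapply(keep, function(s) s$feret_max, numeric(1))
  min_feret <- min(ferets, na.rm = TRUE)
  ratio <- L / min_feret
  warn <- ratio < 10
  if (warn)
    warning("length-to-width aspect ratio ", signif(ratio, 4),
            " is under 10: the no-shear assumption of Euler-Bernoulli ",
            "beam theory may not be met", call. = FALSE)
  structure(list(length_L = L, min_max_feret = min_feret,
                 aspect_ratio = ratio, shear_warning = warn,
                 trim_fraction = 0.05),
            class = "beam_report")
}

#' @export
print.beam_report <- function(x, ...) {
  cat("<beam_report> L = ", signif(x$length_L, 6), " mm; min max-Feret (5% ",
      "trimmed) = ", signif(x$min_max_feret, 6), " mm; aspect ratio = ",
      signif(x$aspect_ratio, 6),
      if (x$shear_warning) " [WARNING: < 10, shear non-negligible]" else
        " [ok]", "\n", sep = "")
  invisible(x)
}
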