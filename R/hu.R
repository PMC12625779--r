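# Hounsfield-unit mixing and cutoff attribution. A voxel spanning two
# materials is assigned the volume-weighted mean of their densities; whether
# the mixed density clears the segmentation cutoff decides which material the
# voxel is counted as.

#' Define a two-material density scenario
#'
#' Describes the clinical density context of a spherical object embedded in a
#' homogeneous matrix: the object density `hu_inside`, the matrix density
#' `hu_outside` and the segmentation cutoff `hu_cutoff`, all in Hounsfield
#' units. The cutoff must lie within the density window spanned by the two
#' materials. Two presets are available via [scenario_preset()].
#'
#' @param hu_inside Object density (HU).
#' @param hu_outside Matrix density (HU).
#' @param hu_cutoff Segmentation cutoff (HU), within the window
#'   `[min(hu_inside, hu_outside), max(hu_inside, hu_outside)]`.
#' @param name Optional label.
#' @return An object of class `"pve_scenario"`.
#' @examples
#' tissue_scenario(1000, 30, 130, "kidney_stone")
#' @export
tissue_scenario <- function(hu_inside, hu_outside, hu_cutoff,
                            name = "custom") {
  stopifnot(is.numeric(hu_inside), is.numeric(hu_outside),
            is.numeric(hu_cutoff))
  if (hu_inside == hu_outside)
    stop("'hu_inside' and 'hu_outside' must differ")
  lo <- min(hu_inside, hu_outside); hi <- max(hu_inside, hu_outside)
  if (hu_cutoff < lo || hu_cutoff > hi)
    stop("'hu_cutoff' must lie within the density window [",
         lo, ", ", hi, "] HU")
  structure(list(hu_inside = hu_inside, hu_outside = hu_outside,
                 hu_cutoff = hu_cutoff, name = name),
            class = "pve_scenario")
}

#' Built-in clinical scenario presets
#'
#' * `"lung_nodule"`: soft-tissue nodule (0 HU) in aerated lung (-1000 HU)
#'   with the standard -500 HU nodule cutoff -- the cutoff sits exactly at the
#'   window midpoint (symmetric threshold).
#' * `"kidney_stone"`: calcified stone (1000 HU) in renal parenchyma / urine
#'   (30 HU) with the 130 HU calcium cutoff -- strongly asymmetric: a voxel
#'   containing barely 10% stone already clears the cutoff.
#'
#' @param name `"lung_nodule"` or `"kidney_stone"`.
#' @return A [tissue_scenario()].
#' @examples
#' scenario_preset("kidney_stone")
#' @export
scenario_preset <- function(name = c("lung_nodule", "kidney_stone")) {
  name <- match.arg(name)
  switch(name,
    lung_nodule  = tissue_scenario(0, -1000, -500, "lung_nodule"),
    kidney_stone = tissue_scenario(1000, 30, 130, "kidney_stone"))
}

#' @export
print.pve_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s': object %g HU in %g HU matrix, cutoff %g HU (p_cutoff = %.4f)\n",
    x$name, x$hu_inside, x$hu_outside, x$hu_cutoff, p_cutoff(x)))
  invisible(x)
}

#' Volume-weighted voxel density
#'
#' The density of a voxel containing a fraction `p1` of the object and
#' `1 - p1` of the matrix: `p1 * hu_inside + (1 - p1) * hu_outside`.
#'
#' @param p1 Object volume fraction(s) in \[0, 1\] (vectorized).
#' @param scenario A [tissue_scenario()].
#' @return Mixed density in HU.
#' @examples
#' mix_hu(0.5, scenario_preset("lung_nodule"))   # -500
#' mix_hu(0.2, scenario_preset("lung_nodule"))   # -800
#' @export
mix_hu <- function(p1, scenario) {
  stopifnot(inherits(scenario, "pve_scenario"))
  if (any(!is.finite(p1)) || any(p1 < 0 | p1 > 1))
    stop("'p1' must lie in [0, 1]")
  p1 * scenario$hu_inside + (1 - p1) * scenario$hu_outside
}

#' Minimal object fraction reaching the segmentation cutoff
#'
#' The object volume fraction at which the mixed voxel density equals the
#' cutoff: `(hu_cutoff - hu_outside) / (hu_inside - hu_outside)`. A voxel with
#' object fraction at or above this value is attributed to the object. For the
#' lung-nodule preset this is 0.5 (cutoff at the window midpoint); for the
#' kidney-stone preset it is 100/970, about 0.103 -- the asymmetry that drives
#' the strong positive PVE of small stones.
#'
#' @inheritParams mix_hu
#' @return Cutoff fraction in \[0, 1\].
#' @examples
#' p_cutoff(scenario_preset("lung_nodule"))    # 0.5
#' p_cutoff(scenario_preset("kidney_stone"))   # 100/970
#' @export
p_cutoff <- function(scenario) {
  stopifnot(inherits(scenario, "pve_scenario"))
  (scenario$hu_cutoff - scenario$hu_outside) /
    (scenario$hu_inside - scenario$hu_outside)
}

#' Attribute a voxel to object or matrix
#'
#' A voxel is attributed to the object when its mixed density lies on the
#' object's side of the cutoff, boundary included: for a bright object in a
#' dark matrix this is `mix_hu(p1) >= hu_cutoff`, equivalently
#' `p1 >= p_cutoff(scenario)`. The fraction-based comparison also covers dark
#' objects in bright matrices (where the HU inequality mirrors).
#'
#' @inheritParams mix_hu
#' @return Character vector, `"object"` or `"matrix"` per element of `p1`.
#' @examples
#' attribute_voxel(0.05, scenario_preset("kidney_stone"))  # "matrix"
#' attribute_voxel(0.15, scenario_preset("kidney_stone"))  # "object"
#' @export
attribute_voxel <- function(p1, scenario) {
  stopifnot(inherits(scenario, "pve_scenario"))
  if (any(!is.finite(p1)) || any(p1 < 0 | p1 > 1))
    stop("'p1' must lie in [0, 1]")
  ifelse(p1 >= p_cutoff(scenario), "object", "matrix")
}

#' Agatston accuracy window for calcification densities
#'
#' Threshold volumetry at the fixed 130 HU calcium cutoff is unbiased only
#' when 130 HU sits at the midpoint of the density window between the
#' calcification and its surroundings. For a matrix density `hu_matrix`
#' (< 130 HU) that happens at the calcification density
#' `130 + (130 - hu_matrix)`; the window of accurately sized densities is
#' symmetric about 130 HU with half-width `130 - hu_matrix`. Calcifications
#' denser than the window's upper bound are increasingly oversized, inflating
#' the Agatston score at exactly the high density factors.
#'
#' @param hu_matrix Density of the material surrounding the calcification
#'   (HU); must be below 130.
#' @return An object of class `"pve_agatston_window"`: list with `hu_matrix`,
#'   `accurate_density`, `window` (low/high bounds) and `density_factor_bins`
#'   (the fixed Agatston peak-density bins).
#' @examples
#' agatston_window(50)    # blood vessel wall: accurate at 210 HU
#' agatston_window(-80)   # pericardial fat: accurate at 340 HU
#' @export
agatston_window <- function(hu_matrix) {
  stopifnot(is.numeric(hu_matrix), length(hu_matrix) == 1L)
  if (!is.finite(hu_matrix) || hu_matrix >= 130)
    stop("'hu_matrix' must be below the 130 HU calcium cutoff")
  half <- 130 - hu_matrix
  structure(list(
    hu_matrix = hu_matrix,
    accurate_density = 130 + half,
    window = c(low = 130 - half, high = 130 + half),
    density_factor_bins = data.frame(
      low = c(130, 200, 300, 400), high = c(199, 299, 399, Inf),
      factor = 1:4)), class = "pve_agatston_window")
}

#' @export
print.pve_agatston_window <- function(x, ...) {
  cat(sprintf(
    "Agatston window for %g HU matrix: accurate at %g HU (window %g..%g HU)\n",
    x$hu_matrix, x$accurate_density, x$window["low"], x$window["high"]))
  invisible(x)
}

#' Agatston density factor of a calcification's peak attenuation
#'
#' The weighting factor applied to the calcified area: 1 for peaks of
#' 130-199 HU, 2 for 200-299, 3 for 300-399 and 4 for 400 HU and above.
#' Peaks below the 130 HU cutoff are not scored and return `NA`.
#'
#' @param peak_hu Peak attenuation(s) of the calcified area (HU, vectorized).
#' @return Integer factor(s) 1-4, or `NA` below 130 HU.
#' @examples
#' agatston_density_factor(c(150, 250, 420))  # 1 2 4
#' @export
agatston_density_factor <- function(peak_hu) {
  f <- findInterval(peak_hu, c(130, 200, 300, 400))
  ifelse(f == 0L, NA_integer_, as.integer(f))
}
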