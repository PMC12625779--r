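#' Define a sphere on the voxel grid
#'
#' A sphere is described by its radius in units of the voxel edge length
#' \eqn{k} (the dimensionless ratio \eqn{r/k}, often written r_norm) and by the
#' displacement of its center from the center of the central voxel. All
#' geometry in this package works in voxel-edge units, so a single simulation
#' applies to any CT geometry; use [rnorm_to_mm()] / [mm_to_rnorm()] to convert
#' to physical units for a given field of view and matrix size.
#'
#' Voxel centers sit at integer lattice points and each voxel occupies the
#' half-open cube \eqn{[i-1/2, i+1/2)} per axis, so the sphere center always
#' lies inside the central voxel \eqn{[-1/2, 1/2)^3}.
#'
#' @param r_norm Positive sphere radius in voxel-edge units (r/k).
#' @param center_offset Numeric length-3 displacement of the sphere center from
#'   the central voxel's center, each component in \[-1/2, 1/2).
#' @return An object of class `"pve_sphere"`: a list with elements `r_norm` and
#'   `center_offset`.
#' @examples
#' sphere(4)
#' sphere(1, center_offset = c(0.3, -0.1, 0.45))
#' @export
sphere <- function(r_norm, center_offset = c(0, 0, 0)) {
  stopifnot(is.numeric(r_norm), length(r_norm) == 1L, is.finite(r_norm))
  if (r_norm <= 0) stop("'r_norm' must be positive")
  center_offset <- as.numeric(center_offset)
  if (length(center_offset) != 3L || any(!is.finite(center_offset)))
    stop("'center_offset' must be a finite numeric vector of length 3")
  if (any(center_offset < -0.5 | center_offset >= 0.5))
    stop("each component of 'center_offset' must lie in [-1/2, 1/2)")
  structure(list(r_norm = r_norm, center_offset = center_offset),
            class = "pve_sphere")
}

#' @export
print.pve_sphere <- function(x, ...) {
  cat(sprintf("Sphere: r/k = %g, center offset = (%g, %g, %g)\n",
              x$r_norm, x$center_offset[1], x$center_offset[2],
              x$center_offset[3]))
  invisible(x)
}

#' Subdivision sampling scheme for cut-voxel volume estimation
#'
#' The intersection volume between a sphere and a cut voxel is estimated by
#' regular subdivision sampling: \eqn{m} evenly spaced sample points per axis
#' (\eqn{m^3} per voxel), each representing a \eqn{(k/m)^3} sub-cube. The
#' default \eqn{m = 5} places the 125 points at offsets
#' \{0, ±1/5, ±2/5\} of the voxel edge from the voxel center along each axis,
#' and the estimated cut fraction is (points inside the sphere) / 125.
#'
#' @param points_per_axis Positive integer \eqn{m}; the scheme uses \eqn{m^3}
#'   sample points per voxel. Default 5 (125 points).
#' @return An object of class `"pve_scheme"`: a list with `points_per_axis` and
#'   `offsets` (the \eqn{m} per-axis offsets from the voxel center, in
#'   voxel-edge units, symmetric about 0 with spacing \eqn{1/m}).
#' @examples
#' sampling_scheme()           # 125 points, offsets -2/5 ... 2/5
#' sampling_scheme(10)         # 1000 points
#' @export
sampling_scheme <- function(points_per_axis = 5L) {
  m <- as.integer(points_per_axis)
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop("'points_per_axis' must be a positive integer")
  offsets <- (seq_len(m) - (m + 1) / 2) / m
  structure(list(points_per_axis = m, offsets = offsets),
            class = "pve_scheme")
}

#' @export
print.pve_scheme <- function(x, ...) {
  cat(sprintf("Subdivision sampling scheme: %d points per axis (%d per voxel)\n",
              x$points_per_axis, x$points_per_axis^3L))
  invisible(x)
}
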