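# Scenario sweeps over the clinically relevant radius range and conversion
# between voxel-edge units and millimetres for a given CT geometry.

#' CT reconstruction geometry
#'
#' The voxel edge length of an isotropic reconstruction is the field of view
#' divided by the matrix size. The defaults (350 mm FOV, 512 matrix)
#' correspond to an average adult abdominal or chest CT with a voxel edge of
#' about 0.68 mm; a typical head CT (200 mm FOV) gives about 0.39 mm.
#'
#' @param fov_mm Field of view in millimetres.
#' @param matrix_size Reconstruction matrix size (pixels per row).
#' @return An object of class `"pve_geometry"` with `fov_mm`, `matrix_size`
#'   and the derived `voxel_edge_mm`.
#' @examples
#' ct_geometry()$voxel_edge_mm            # ~0.68
#' ct_geometry(fov_mm = 200)$voxel_edge_mm  # ~0.39
#' @export
ct_geometry <- function(fov_mm = 350, matrix_size = 512L) {
  stopifnot(is.numeric(fov_mm), fov_mm > 0,
            is.numeric(matrix_size), matrix_size >= 1)
  structure(list(fov_mm = fov_mm, matrix_size = as.integer(matrix_size),
                 voxel_edge_mm = fov_mm / matrix_size),
            class = "pve_geometry")
}

#' @export
print.pve_geometry <- function(x, ...) {
  cat(sprintf("CT geometry: FOV %g mm / %d matrix -> voxel edge %.4f mm\n",
              x$fov_mm, x$matrix_size, x$voxel_edge_mm))
  invisible(x)
}

#' Convert an object diameter in millimetres to a normalized radius
#'
#' @param diameter_mm Object diameter in millimetres.
#' @param geometry A [ct_geometry()].
#' @return The radius in voxel-edge units, `diameter_mm / (2 * voxel_edge_mm)`.
#' @examples
#' mm_to_rnorm(1.4)    # ~1 at default geometry
#' mm_to_rnorm(95.7)   # ~70
#' @export
mm_to_rnorm <- function(diameter_mm, geometry = ct_geometry()) {
  stopifnot(inherits(geometry, "pve_geometry"))
  if (any(diameter_mm <= 0)) stop("'diameter_mm' must be positive")
  diameter_mm / (2 * geometry$voxel_edge_mm)
}

#' Convert a normalized radius to an object diameter in millimetres
#'
#' @param r_norm Radius in voxel-edge units.
#' @param geometry A [ct_geometry()].
#' @return The diameter in millimetres, `2 * r_norm * voxel_edge_mm`.
#' @examples
#' rnorm_to_mm(1)   # ~1.37 mm at default geometry
#' @export
rnorm_to_mm <- function(r_norm, geometry = ct_geometry()) {
  stopifnot(inherits(geometry, "pve_geometry"))
  if (any(r_norm <= 0)) stop("'r_norm' must be positive")
  2 * r_norm * geometry$voxel_edge_mm
}

#' Default radius sweep of the scenario tables
#'
#' Radii 1-10 in unit steps and 20-70 in steps of 10, in voxel-edge units.
#' @return Numeric vector of radii.
#' @export
default_radii <- function() c(1:10, seq(20, 70, by = 10))

#' Simulate a full scenario table over a radius sweep
#'
#' Runs [run_simulation()] once per radius and collects the summary rows,
#' together with the physical object diameter at the given CT geometry. The
#' `"geometry_only"` scenario reports the geometric approximation ratio
#' `P_approx`; `"lung_nodule"` and `"kidney_stone"` additionally report the
#' threshold-volumetry ratio `P_sim`.
#'
#' @param scenario_name One of `"geometry_only"`, `"lung_nodule"`,
#'   `"kidney_stone"`.
#' @param radii Radius sweep in voxel-edge units (default [default_radii()]).
#' @param geometry A [ct_geometry()] used for the diameter column.
#' @param repetitions Monte-Carlo repetitions per radius (default 100).
#' @param scheme A [sampling_scheme()].
#' @param seed Optional integer seed; each radius uses an independent
#'   sub-stream derived from it, so a subset of radii reproduces the
#'   corresponding rows of the full sweep.
#' @return An object of classes `"pve_table"` and `data.frame`: one row per
#'   radius with columns `r_norm`, `diameter_mm`, `n_I`, `n_T`, `pct_Vr`,
#'   `mean_Vcut`, `V_r_sphere_norm`, `V_m_sphere`, `P_approx`, `n_sphere`,
#'   `V_m_CT`, `P_sim`, standard-deviation companions and `repetitions`.
#'   Attributes `scenario_name` and `geometry` carry the inputs.
#' @examples
#' build_table("kidney_stone", radii = 1:3, repetitions = 10, seed = 1)
#' @export
build_table <- function(scenario_name = c("geometry_only", "lung_nodule",
                                          "kidney_stone"),
                        radii = default_radii(), geometry = ct_geometry(),
                        repetitions = 100L, scheme = sampling_scheme(),
                        seed = NULL) {
  scenario_name <- match.arg(scenario_name)
  scenario <- if (scenario_name == "geometry_only") NULL
              else scenario_preset(scenario_name)
  radii <- as.numeric(radii)
  if (any(radii <= 0)) stop("'radii' must be positive")
  radii <- sort(radii)
  rows <- lapply(radii, function(r) {
    row_seed <- if (is.null(seed)) NULL
                else (as.integer(seed) + round(1000 * r)) %% .Machine$integer.max
    run_simulation(simulation_config(
      r_norm = r, scenario = scenario, repetitions = repetitions,
      scheme = scheme, seed = row_seed))$summary
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(r_norm = tab$r_norm,
               diameter_mm = rnorm_to_mm(tab$r_norm, geometry),
               tab[-1L])
  attr(tab, "scenario_name") <- scenario_name
  attr(tab, "geometry") <- geometry
  class(tab) <- c("pve_table", "data.frame")
  tab
}

#' @export
print.pve_table <- function(x, digits = NULL, ...) {
  scen <- attr(x, "scenario_name")
  cat(sprintf("PVE scenario table: %s (%d radii, %d repetitions)\n",
              scen, nrow(x), x$repetitions[1]))
  ratio <- if (scen == "geometry_only") "P_approx" else "P_sim"
  disp <- data.frame(
    `r/k` = x$r_norm,
    diameter_mm = sprintf("%.1f", x$diameter_mm),
    n_I = sprintf("%.1f", x$n_I), n_T = sprintf("%.1f", x$n_T),
    pct_Vr = round(x$pct_Vr), mean_Vcut = sprintf("%.2f", x$mean_Vcut),
    V_r = sprintf("%.1f", x$V_r_sphere_norm),
    V_m = sprintf("%.1f", x$V_m_sphere),
    check.names = FALSE)
  disp[[ratio]] <- sprintf("%.2f", x[[ratio]])
  print(disp, row.names = FALSE)
  invisible(x)
}
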