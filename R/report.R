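# Output writers: CSV/JSON tables, run manifests and NIfTI phantom volumes.

#' Write a scenario table as CSV and JSON with a run manifest
#'
#' Writes the table to `<basename>.csv` and `<basename>.json` (full numeric
#' precision in both) and a `<basename>_manifest.json` recording the
#' configuration needed to reproduce the files bit-identically: scenario,
#' radii, repetitions, sampling scheme, seed, package version and the output
#' paths. The manifest's timestamp is the only non-reproducible field, and it
#' lives only in the manifest.
#'
#' @param table A [build_table()] result.
#' @param dir Output directory (created if missing).
#' @param basename File stem; defaults to the table's scenario name.
#' @param seed The seed the table was built with, echoed into the manifest.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_scenario_table <- function(table, dir = ".", basename = NULL,
                                 seed = NULL) {
  stopifnot(inherits(table, "pve_table"))
  if (is.null(basename)) basename <- attr(table, "scenario_name")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(csv = file.path(dir, paste0(basename, ".csv")),
             json = file.path(dir, paste0(basename, ".json")),
             manifest = file.path(dir, paste0(basename, "_manifest.json")))
  df <- as.data.frame(table)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   paths["csv"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(df, paths["json"], digits = NA, dataframe = "rows")
  geometry <- attr(table, "geometry")
  manifest <- list(
    tool = "pvesim", version = as.character(utils::packageVersion("pvesim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(
      scenario = attr(table, "scenario_name"),
      radii = table$r_norm, repetitions = table$repetitions[1],
      seed = seed,
      fov_mm = geometry$fov_mm, matrix_size = geometry$matrix_size),
    outputs = as.list(paths[c("csv", "json")]))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

#' Render a sphere into a Hounsfield-unit voxel volume
#'
#' Builds the 3-D HU volume of the sphere's bounding grid -- `hu_inside` for
#' fully-inside voxels, `hu_outside` for outside voxels and the mixed density
#' [mix_hu()] for cut voxels -- and writes it as a NIfTI file with the
#' isotropic voxel spacing of the given geometry recorded in the header.
#' Useful for visual inspection in standard medical-imaging viewers and for
#' cross-checking the simulator against third-party threshold tools.
#'
#' @param sphere A [sphere()].
#' @param scenario A [tissue_scenario()].
#' @param scheme A [sampling_scheme()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param geometry A [ct_geometry()] supplying the voxel edge in mm.
#' @return Invisibly, the 3-D HU array that was written (dimensions
#'   `(2H+1)^3` with `H = ceiling(r_norm) + 1`).
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".nii.gz")
#' vol <- export_phantom(sphere(4), scenario_preset("lung_nodule"), path = f)
#' sum(vol >= -500)  # voxels a -500 HU threshold attributes to the nodule
#' }
#' @export
export_phantom <- function(sphere, scenario, scheme = sampling_scheme(),
                           path, geometry = ct_geometry()) {
  stopifnot(inherits(sphere, "pve_sphere"),
            inherits(scenario, "pve_scenario"),
            inherits(scheme, "pve_scheme"),
            inherits(geometry, "pve_geometry"))
  cl <- classify_grid(sphere, scheme)
  H <- as.integer(ceiling(sphere$r_norm)) + 1L
  n <- 2L * H + 1L
  vol <- array(scenario$hu_outside, dim = c(n, n, n))
  to_lin <- function(idx) {
    (idx[, 1] + H + 1L) + n * (idx[, 2] + H) + n * n * (idx[, 3] + H)
  }
  if (cl$n_I > 0) vol[to_lin(cl$inside)] <- scenario$hu_inside
  if (cl$n_T > 0) vol[to_lin(cl$cut)] <- mix_hu(cl$cut_fraction, scenario)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(geometry$voxel_edge_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(vol)
}
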