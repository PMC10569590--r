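#' Concentric-sphere cell geometry
#'
#' The microorganism is a water sphere of radius `r_microorganism` holding a
#' concentric water nucleus of radius `r_nucleus`; diatoms additionally carry
#' a silica frustule shell of thickness `frustule_thickness` around the
#' microorganism. The surrounding environment is a sphere whose radius
#' defaults to [environment_radius()] evaluated with the water range of the
#' most energetic built-in alpha line (5.490 MeV, 43.44 um), so that the
#' environment contains every point from which an alpha can still reach the
#' diatom. The same `r_max` is used for every environment composition, which
#' reproduces the standard 55 um (57.1 um with frustule) setup.
#'
#' Coordinates are Cartesian micrometres with the origin at the common centre
#' of the spheres; directions are unit vectors.
#'
#' @param r_nucleus nucleus radius in um (default 0.5)
#' @param r_microorganism microorganism radius in um (default 10)
#' @param frustule_thickness frustule shell thickness in um (0 = none)
#' @param environment_material [material()] filling the environment sphere
#' @param frustule_material [material()] of the frustule shell
#' @param r_max water range used to size the environment (um); defaults to
#'   the range of the most energetic built-in line under `model`
#' @param r_env environment radius (um); overrides the formula if given
#' @param model [range_energy_model()] used for the default `r_max`
#' @return object of class `cell_geometry`
#' @examples
#' cell_geometry()                          # water-column setup, R_env ~ 55
#' cell_geometry(frustule_thickness = 2)    # frustuled diatom, R_env ~ 57.1
#' @export
cell_geometry <- function(r_nucleus = 0.5, r_microorganism = 10,
                          frustule_thickness = 0,
                          environment_material = water_material(),
                          frustule_material = silicate_material(),
                          r_max = NULL, r_env = NULL,
                          model = default_range_model()) {
  if (is.null(r_max)) {
    e_max <- max(vapply(builtin_spectra(), function(s) max(s$lines$energy),
                        numeric(1)))
    r_max <- csda_range(e_max, model)
  }
  if (is.null(r_env)) {
    r_env <- environment_radius(r_max, r_microorganism, frustule_thickness)
  }
  r_out <- r_microorganism + frustule_thickness
  if (!(r_nucleus > 0 && r_nucleus < r_microorganism &&
        r_microorganism <= r_out && r_out < r_env)) {
    stop("radii must satisfy 0 < r_nucleus < r_microorganism <= ",
         "r_microorganism + frustule_thickness < r_env")
  }
  structure(list(
    r_nucleus = r_nucleus,
    r_microorganism = r_microorganism,
    frustule_thickness = frustule_thickness,
    r_outer = r_out,
    r_env = r_env,
    r_max = r_max,
    environment_material = environment_material,
    frustule_material = frustule_material
  ), class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("cell geometry (concentric spheres, um):\n")
  cat(sprintf("  nucleus %.2f | microorganism %.2f | frustule %.2f | environment %.2f\n",
              x$r_nucleus, x$r_microorganism, x$frustule_thickness, x$r_env))
  cat(sprintf("  environment: %s (rho %.2f, msr %.2f)\n",
              x$environment_material$name, x$environment_material$density,
              x$environment_material$mass_stopping_ratio))
  if (x$frustule_thickness > 0) {
    cat(sprintf("  frustule: %s (rho %.2f, msr %.2f)\n",
                x$frustule_material$name, x$frustule_material$density,
                x$frustule_material$mass_stopping_ratio))
  }
  invisible(x)
}
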