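#' Alpha decay spectra
#'
#' An alpha spectrum is a set of discrete emission lines (energy in MeV,
#' intensity in percent per decay). Each decay emits exactly one alpha, so
#' line intensities must sum to 100% within 0.1 percentage points.
#' `builtin_spectra()` returns the evaluated decay data used throughout:
#' three lines for Rn-222 (dominant 5.490 MeV, 99.92%) and five for Ra-226
#' (dominant 4.784 MeV, 93.84%). Daughter nuclides are not included.
#'
#' @param nuclide nuclide label, e.g. `"Rn-222"`
#' @param energy numeric vector of line energies (MeV, > 0)
#' @param intensity numeric vector of line intensities (% per decay)
#' @return `alpha_spectrum` object with elements `nuclide` and `lines`
#'   (data.frame with columns `energy`, `intensity`)
#' @examples
#' sp <- builtin_spectra()
#' sp$rn222$lines
#' @export
alpha_spectrum <- function(nuclide, energy, intensity) {
  stopifnot(length(energy) == length(intensity), length(energy) >= 1)
  if (any(energy <= 0)) stop("line energies must be positive")
  if (any(intensity <= 0) || any(intensity > 100)) {
    stop("line intensities must be in (0, 100] percent")
  }
  tot <- sum(intensity)
  if (tot < 99.9 || tot > 100.1) {
    stop(sprintf("line intensities sum to %.3f%%; expected 100%% +/- 0.1", tot))
  }
  structure(list(nuclide = nuclide,
                 lines = data.frame(energy = energy, intensity = intensity)),
            class = "alpha_spectrum")
}

#' @rdname alpha_spectrum
#' @export
builtin_spectra <- function() {
  list(
    rn222 = alpha_spectrum("Rn-222",
                           energy = c(4.826, 4.986, 5.490),
                           intensity = c(5.0e-04, 0.078, 99.92)),
    ra226 = alpha_spectrum("Ra-226",
                           energy = c(4.160, 4.191, 4.340, 4.601, 4.784),
                           intensity = c(2.7e-04, 1.0e-03, 6.5e-03, 6.16, 93.84))
  )
}

#' Read a custom alpha spectrum from a two-column text table
#'
#' The file must be whitespace- or comma-separated with two columns: energy
#' in MeV and intensity in percent per decay. Lines starting with `#` are
#' comments.
#'
#' @param path file path
#' @param nuclide label for the resulting spectrum
#' @return an [alpha_spectrum()]
#' @export
read_spectrum <- function(path, nuclide = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", fill = FALSE)
  if (ncol(tab) == 1) {
    tab <- utils::read.csv(path, header = FALSE, comment.char = "#")
  }
  if (ncol(tab) < 2) stop("spectrum file must have two columns (MeV, %)")
  alpha_spectrum(nuclide, as.numeric(tab[[1]]), as.numeric(tab[[2]]))
}

#' Sample alpha emission lines from a spectrum
#'
#' Draws `n` lines with probability proportional to line intensity and
#' returns their energies (MeV). Uses the current RNG state.
#'
#' @param spectrum an [alpha_spectrum()]
#' @param n number of decays to sample
#' @return numeric vector of `n` emission energies
#' @export
sample_decay <- function(spectrum, n = 1) {
  lines <- spectrum$lines
  if (is.null(lines) || nrow(lines) == 0) stop("empty spectrum")
  if (nrow(lines) == 1) return(rep(lines$energy, n))
  idx <- sample.int(nrow(lines), n, replace = TRUE, prob = lines$intensity)
  lines$energy[idx]
}

#' Sample alpha emission points and directions in the environment
#'
#' Emission points are uniform over the environment sphere excluding the
#' diatom (radii in `(r_outer, r_env]`); directions are isotropic over 4pi.
#' With `toward_nucleus = TRUE` the directions are instead drawn uniformly
#' within the cone subtended by the nucleus as seen from the emission point,
#' and each emission carries the statistical weight `omega/4pi` of that cone
#' (the conditional distribution of nucleus-aimed tracks is unchanged). This
#' forced-detection mode drives the nanodosimetric stage efficiently.
#'
#' @param geometry a [cell_geometry()]
#' @param n number of emissions
#' @param toward_nucleus logical; sample directions in the nucleus cone with
#'   matching statistical weights
#' @return list with `position` (n x 3, um), `direction` (n x 3 unit rows)
#'   and `weight` (length n; all 1 in analog mode)
#' @export
sample_emission <- function(geometry, n, toward_nucleus = FALSE) {
  stopifnot(inherits(geometry, "cell_geometry"), n >= 1)
  r_in <- geometry$r_outer
  r_env <- geometry$r_env
  d <- (r_in^3 + stats::runif(n) * (r_env^3 - r_in^3))^(1 / 3)
  # isotropic emission point at radius d
  pos <- .isotropic_directions(n) * d
  if (!toward_nucleus) {
    dir <- .isotropic_directions(n)
    weight <- rep(1, n)
  } else {
    mu0 <- sqrt(1 - (geometry$r_nucleus / d)^2)
    mu <- mu0 + stats::runif(n) * (1 - mu0)
    weight <- (1 - mu0) / 2
    dir <- .cone_directions(-pos / d, mu)
  }
  list(position = pos, direction = dir, weight = weight)
}

# n isotropic unit vectors (n x 3)
.isotropic_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

# unit vectors at polar cosine mu around per-row unit axes (n x 3)
.cone_directions <- function(axis, mu) {
  n <- nrow(axis)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - mu^2, 0))
  # build an orthonormal basis (e1, e2) perpendicular to each axis
  h <- abs(axis[, 1]) < 0.9
  helper <- cbind(ifelse(h, 1, 0), ifelse(h, 0, 1), 0)
  e1 <- .cross(axis, helper)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- .cross(axis, e1)
  axis * mu + e1 * (s * cos(phi)) + e2 * (s * sin(phi))
}

.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Activity scenario: radionuclide concentrations around a microorganism
#'
#' Couples the measured activity concentrations (Rn-222 in the water phase,
#' Bq/L; Ra-226 in the dry sediment, Bq/g) with a porosity and a geometry.
#' Rn-222 can only be present if there is water (porosity > 0) and Ra-226
#' only if there is sediment (porosity < 100).
#'
#' @param c_rn Rn-222 activity concentration in the water phase (Bq/L)
#' @param c_ra Ra-226 mass activity of the dry sediment (Bq/g)
#' @param porosity volume percent of water in the environment, in [0, 100]
#' @param geometry a [cell_geometry()]; its environment material should match
#'   the porosity (use [mixture_material()])
#' @param sediment sediment [material()] supplying the dry density used to
#'   convert Bq/g to total activity
#' @param include_diatom_volume if TRUE, normalise activity over the full
#'   environment sphere instead of the sphere minus the diatom (the two
#'   conventions differ by ~1%)
#' @return object of class `activity_scenario`
#' @export
activity_scenario <- function(c_rn = 0, c_ra = 0, porosity = 100,
                              geometry = cell_geometry(),
                              sediment = sediment_material(),
                              include_diatom_volume = FALSE) {
  if (c_rn < 0 || c_ra < 0) stop("activity concentrations must be >= 0")
  if (porosity < 0 || porosity > 100) stop("porosity must be in [0, 100]")
  if (c_rn > 0 && porosity == 0) {
    stop("Rn-222 requires water: porosity must be > 0")
  }
  if (c_ra > 0 && porosity == 100) {
    stop("Ra-226 requires sediment: porosity must be < 100")
  }
  structure(list(c_rn = c_rn, c_ra = c_ra, porosity = porosity,
                 geometry = geometry, sediment = sediment,
                 include_diatom_volume = include_diatom_volume),
            class = "activity_scenario")
}

#' Total source activity per nuclide in the environment
#'
#' The source region is the environment sphere minus the diatom volume (or
#' the full sphere if `include_diatom_volume`). Rn-222 activity is
#' `c_rn * (P/100) * V[L]`; Ra-226 activity is
#' `c_ra * (1 - P/100) * rho_sediment * V[cm^3]`.
#'
#' @param scenario an [activity_scenario()]
#' @return named numeric vector `c(rn222 = , ra226 = )` in Bq
#' @export
total_activity <- function(scenario) {
  stopifnot(inherits(scenario, "activity_scenario"))
  g <- scenario$geometry
  v_um3 <- (4 / 3) * pi *
    (g$r_env^3 - if (scenario$include_diatom_volume) 0 else g$r_outer^3)
  v_cm3 <- v_um3 * .UM3_TO_CM3
  v_l <- v_cm3 * .CM3_TO_L
  fw <- scenario$porosity / 100
  c(rn222 = scenario$c_rn * fw * v_l,
    ra226 = scenario$c_ra * (1 - fw) * scenario$sediment$density * v_cm3)
}

#' @export
print.activity_scenario <- function(x, ...) {
  act <- total_activity(x)
  cat(sprintf("activity scenario: porosity %g%%, Rn-222 %g Bq/L, Ra-226 %g Bq/g\n",
              x$porosity, x$c_rn, x$c_ra))
  cat(sprintf("  total source activity: Rn-222 %.3e Bq, Ra-226 %.3e Bq\n",
              act["rn222"], act["ra226"]))
  invisible(x)
}
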