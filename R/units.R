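# Physical constants and unit conversions used across the package.
# Lengths are micrometres at the cell scale and nanometres at the DNA scale;
# energies are MeV at the cell scale and eV at the DNA scale.

.MEV_TO_J <- 1.602176634e-13
.EV_TO_J <- 1.602176634e-19
.UM3_TO_CM3 <- 1e-12
.CM3_TO_L <- 1e-3
.HOUR_S <- 3600

# mass (kg) of a sphere of radius r_um at density g/cm^3
.sphere_mass_kg <- function(r_um, density = 1.0) {
  (4 / 3) * pi * r_um^3 * .UM3_TO_CM3 * density * 1e-3
}

# mass (kg) of a spherical shell between r1_um and r2_um
.shell_mass_kg <- function(r1_um, r2_um, density = 1.0) {
  .sphere_mass_kg(r2_um, density) - .sphere_mass_kg(r1_um, density)
}

# mass (kg) of a cylinder given radius/height in nm at density g/cm^3
.cylinder_mass_kg <- function(radius_nm, height_nm, density = 1.0) {
  pi * radius_nm^2 * height_nm * 1e-21 * density * 1e-3
}
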