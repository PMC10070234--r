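# Physical constants in the wavenumber/femtosecond/Angstrom/Debye unit system
# used throughout the package.

# speed of light [cm/fs]; phase factors are exp(-2i*pi*c*nu*t) with nu in cm^-1
.c_cm_fs <- 2.99792458e-5

# Boltzmann constant [cm^-1/K]
.kB_cm <- 0.695034800

# point-dipole coupling prefactor [cm^-1 * Angstrom^3 / Debye^2]
.kappa_dd <- 5034.0

#' Convert a wavenumber to a vacuum wavelength
#'
#' @param wavenumber Wavenumber(s) in cm^-1; must be positive.
#' @return Wavelength(s) in nm (`1e7 / wavenumber`).
#' @examples
#' wavenumber_to_nm(14910) # 670.7 nm, red edge of the chlorophyll a Qy band
#' @export
wavenumber_to_nm <- function(wavenumber) {
  if (any(!is.finite(wavenumber)) || any(wavenumber <= 0)) {
    stop("`wavenumber` must be positive and finite", call. = FALSE)
  }
  1e7 / wavenumber
}

#' Convert a relaxation rate in cm^-1 to a time constant in fs
#'
#' @param rate_cm Rate (HWHM-type linewidth) in cm^-1.
#' @return Time constant in fs, `1 / (2 pi c rate)`.
#' @keywords internal
rate_to_fs <- function(rate_cm) 1 / (2 * pi * .c_cm_fs * rate_cm)
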