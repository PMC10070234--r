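#' Electronic state table
#'
#' Builds the table of singlet excited states entering the monomer
#' Hamiltonian.  Energies are 0-0 offsets relative to Qy in cm^-1; dipole
#' strengths are given as ratios f = |mu_state|^2 / |mu_Qy|^2 (transition
#' dipole *amplitudes* scale with sqrt(f)).  Only Qy and Qx carry
#' vibrational structure and only they are mixed by the vibronic coupling
#' mode; By and Bx are purely electronic.
#'
#' @param states Character vector naming the included states; must contain
#'   `"Qy"` and be a subset of `c("Qy","Qx","By","Bx")`.
#' @param dE_QxQy,dE_ByQy,dE_BxQy 0-0 energy offsets relative to Qy (cm^-1).
#' @param f_QxQy,f_ByQy,f_BxQy Dipole-strength ratios relative to Qy.
#' @return Data frame with columns `label`, `energy_offset`,
#'   `dipole_ratio_sq`, `has_vibrations`, `vibronically_coupled`.
#' @export
electronic_states <- function(states = c("Qy", "Qx", "By", "Bx"),
                              dE_QxQy = 1640, dE_ByQy = 7570, dE_BxQy = 8740,
                              f_QxQy = 0.1, f_ByQy = 2.52, f_BxQy = 2.43) {
  all <- data.frame(
    label = c("Qy", "Qx", "By", "Bx"),
    energy_offset = c(0, dE_QxQy, dE_ByQy, dE_BxQy),
    dipole_ratio_sq = c(1, f_QxQy, f_ByQy, f_BxQy),
    has_vibrations = c(TRUE, TRUE, FALSE, FALSE),
    vibronically_coupled = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(states, all$label)
  if (length(bad)) stop("unknown electronic state(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!"Qy" %in% states) stop("the state set must contain Qy", call. = FALSE)
  out <- all[all$label %in% states, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Vibronic coupling mode parameters
#'
#' The single mode mediating non-adiabatic Qy-Qx mixing, analogous to the
#' coupling mode of a conical intersection.  The coupling is linear in the
#' mode coordinate; its oscillator potentials are *not* displaced between
#' electronic states, so all Franck-Condon activity of this mode is induced
#' by the off-diagonal coupling.  `coupling_scaled` is the coupling constant
#' expressed for the frequency-scaled coordinate (alpha-tilde, in cm^-1);
#' the unscaled constant is `alpha = alpha_tilde * sqrt(omega_VC)`.
#'
#' @param frequency Mode frequency omega_VC in cm^-1.
#' @param coupling_scaled Scaled vibronic coupling constant in cm^-1.
#' @param max_quanta Highest vibrational quantum of this mode kept in the
#'   basis (default 4).
#' @return A list of class `vc_mode`.
#' @export
vc_mode <- function(frequency = 1500, coupling_scaled = 750, max_quanta = 4) {
  if (frequency <= 0) stop("`frequency` must be > 0", call. = FALSE)
  if (max_quanta < 0) stop("`max_quanta` must be >= 0", call. = FALSE)
  structure(list(frequency = frequency, coupling_scaled = coupling_scaled,
                 max_quanta = as.integer(max_quanta)),
            class = "vc_mode")
}

#' Bath (spectral density) parameters
#'
#' Two-term super-Ohmic spectral density of the low-frequency
#' pigment-protein bath,
#' `J(w) = sum_k s_k w^3 / (7! * 2 * w_k^4) * exp(-sqrt(w / w_k))`,
#' normalized so that `integral J dw = s1 + s2` (the bath Huang-Rhys
#' factor) and `integral w J dw = 72 (s1 w1 + s2 w2)` (the bath
#' reorganization energy).  Defaults give a total Huang-Rhys factor 0.8.
#'
#' @param s1,s2 Dimensionless Huang-Rhys weights.
#' @param omega1,omega2 Characteristic frequencies in cm^-1.
#' @param temperature Bath temperature in K.
#' @param tau_max_fs Cap on the dephasing time of weakly relaxing states
#'   (default 10 ps) keeping Fourier transforms finite.
#' @return A list of class `bath_params`.
#' @export
bath_params <- function(s1 = 0.402, s2 = 0.398, omega1 = 0.557, omega2 = 1.94,
                        temperature = 300, tau_max_fs = 1e4) {
  if (any(c(s1, s2) < 0) || any(c(omega1, omega2) <= 0)) {
    stop("bath weights must be >= 0 and frequencies > 0", call. = FALSE)
  }
  if (temperature <= 0) stop("`temperature` must be > 0", call. = FALSE)
  structure(list(s1 = s1, s2 = s2, omega1 = omega1, omega2 = omega2,
                 temperature = temperature, tau_max_fs = tau_max_fs),
            class = "bath_params")
}

#' Gaussian site-energy disorder model
#'
#' Static disorder of the local 0-0 transition energies.  Each pigment and
#' each electronic state receives an independent Gaussian shift with the
#' per-state FWHM; `sigma = FWHM / (2 sqrt(2 log 2))`.
#'
#' @param fwhm Named numeric vector of FWHM values in cm^-1, names among
#'   `Qy`, `Qx`, `By`, `Bx`; missing states default to 0 (no disorder).
#' @param n_samples Number of Monte-Carlo realizations.
#' @param seed Integer seed making the Monte-Carlo average reproducible.
#' @param correlated_qx If `TRUE`, the Qx shift of a pigment is tied to its
#'   Qy shift (scaled by the FWHM ratio) instead of drawn independently.
#'   Default `FALSE` (independent draws).
#' @return A list of class `disorder_model`.
#' @export
disorder_model <- function(fwhm = c(Qy = 170, Qx = 340, By = 1800, Bx = 1800),
                           n_samples = 1000, seed = 1L, correlated_qx = FALSE) {
  fwhm <- unlist(fwhm)
  if (is.null(names(fwhm)) || any(!names(fwhm) %in% c("Qy", "Qx", "By", "Bx"))) {
    stop("`fwhm` must be named with states among Qy, Qx, By, Bx", call. = FALSE)
  }
  if (any(fwhm < 0)) stop("FWHM values must be >= 0", call. = FALSE)
  full <- c(Qy = 0, Qx = 0, By = 0, Bx = 0)
  full[names(fwhm)] <- fwhm
  structure(list(fwhm = full, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), correlated_qx = isTRUE(correlated_qx)),
            class = "disorder_model")
}

#' Full monomer parameter set
#'
#' @param states An [electronic_states()] table.
#' @param modes A [mode_catalog()].
#' @param vc A [vc_mode()]; set `coupling_scaled = 0` to switch the vibronic
#'   coupling off.
#' @param qy_energy_absolute Absolute 0-0 energy of Qy in cm^-1 (used only to
#'   place output spectra on an absolute axis; internally all energies are
#'   relative to the Qy 0-0 line).
#' @param inhomogeneous_fwhm Named FWHM vector, as in [disorder_model()].
#' @return A list of class `monomer_params`.
#' @export
monomer_params <- function(states = electronic_states(),
                           modes = chla_mode_catalog(),
                           vc = vc_mode(),
                           qy_energy_absolute = 14910,
                           inhomogeneous_fwhm = c(Qy = 240, Qx = 720,
                                                  By = 1800, Bx = 1800)) {
  stopifnot(inherits(modes, "mode_catalog"), inherits(vc, "vc_mode"))
  vib_states <- states$label[states$has_vibrations]
  for (s in vib_states) {
    col <- paste0("S_", s)
    if (!col %in% names(modes)) {
      stop("mode catalog lacks Huang-Rhys column for state ", s, call. = FALSE)
    }
  }
  full <- c(Qy = 0, Qx = 0, By = 0, Bx = 0)
  inhomogeneous_fwhm <- unlist(inhomogeneous_fwhm)
  full[names(inhomogeneous_fwhm)] <- inhomogeneous_fwhm
  structure(list(states = states, modes = modes, vc = vc,
                 qy_energy_absolute = qy_energy_absolute,
                 inhomogeneous_fwhm = full),
            class = "monomer_params")
}

#' @export
print.monomer_params <- function(x, ...) {
  cat("Monomer parameter set\n")
  cat("  states:", paste(x$states$label, collapse = ", "), "\n")
  cat(sprintf("  Qy 0-0 at %.0f cm^-1 (%.1f nm)\n", x$qy_energy_absolute,
              wavenumber_to_nm(x$qy_energy_absolute)))
  cat(sprintf("  %d intramolecular modes, total S(Qy) = %.3f\n",
              nrow(x$modes), sum(x$modes$S_Qy)))
  cat(sprintf("  vibronic coupling: alpha~ = %.0f cm^-1, omega_VC = %.0f cm^-1, <= %d quanta\n",
              x$vc$coupling_scaled, x$vc$frequency, x$vc$max_quanta))
  invisible(x)
}
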