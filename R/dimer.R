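# Calibrated orientation of the synthetic C2 "open sandwich" dimer (degrees);
# see the methods vignette for the calibration against the WSCP coupling table.
.open_sandwich_defaults <- c(tilt = -96.507977, twist = 80.331394,
                             azimuth = -27.054422, skew = -1.837764)

#' Orientation factor of the point-dipole coupling
#'
#' `zeta = e_m . e_n - 3 (e_m . e_ab)(e_n . e_ab)` for unit dipole
#' directions `e_m`, `e_n` and the unit center-connecting vector `e_ab`.
#'
#' @param e_m,e_n Unit dipole direction vectors.
#' @param e_ab Unit vector from center a to center b.
#' @return Dimensionless orientation factor in `[-2, 2]`.
#' @export
orientation_factor <- function(e_m, e_n, e_ab) {
  sum(e_m * e_n) - 3 * sum(e_m * e_ab) * sum(e_n * e_ab)
}

#' Point-dipole excitonic coupling between two localized transitions
#'
#' `J = kappa * mu_a * mu_b * zeta / R^3` with
#' `kappa = 5034 cm^-1 A^3 / D^2` (vacuum; no screening factor).
#'
#' @param geom_a,geom_b [pigment_geometry()] objects.
#' @param state_a,state_b Transition labels (`"Qy"`, `"Qx"`, `"By"`, `"Bx"`).
#' @param mu_a,mu_b Transition-dipole magnitudes in Debye.
#' @return Coupling in cm^-1.
#' @export
dipole_dipole_coupling <- function(geom_a, geom_b, state_a = "Qy",
                                   state_b = "Qy", mu_a = 1, mu_b = 1) {
  dr <- geom_b$center - geom_a$center
  R <- sqrt(sum(dr^2))
  if (R == 0) stop("pigment centers coincide", call. = FALSE)
  e_ab <- dr / R
  z <- orientation_factor(dipole_directions(geom_a)[state_a, ],
                          dipole_directions(geom_b)[state_b, ], e_ab)
  .kappa_dd * mu_a * mu_b * z / R^3
}

#' Excitonic coupling matrix anchored to the fitted Qy-Qy coupling
#'
#' Rather than using absolute point-dipole couplings, all couplings are
#' scaled from the fitted Qy-Qy value:
#' `J_mn = J_QyQy * f_m * f_n * zeta_mn / zeta_QyQy`, where `f_k` is the
#' transition-dipole *amplitude* ratio `mu_k / mu_Qy` (the square root of
#' the dipole-strength ratio) and the zetas are orientation factors of the
#' rotated dipole directions.  The point-dipole prefactor and the absolute
#' dipole magnitudes cancel.
#'
#' @param geom_a,geom_b [pigment_geometry()] objects.
#' @param states An [electronic_states()] table supplying the `f` ratios.
#' @param J_QyQy Anchor coupling in cm^-1 (default 83, the fitted WSCP
#'   value).
#' @return Matrix `J[m, n]` (cm^-1) over the states of pigment a (rows) and
#'   pigment b (columns), class `coupling_matrix`.
#' @export
scaled_couplings <- function(geom_a, geom_b, states = electronic_states(),
                             J_QyQy = 83) {
  dr <- geom_b$center - geom_a$center
  R <- sqrt(sum(dr^2))
  if (R == 0) stop("pigment centers coincide", call. = FALSE)
  e_ab <- dr / R
  da <- dipole_directions(geom_a)
  db <- dipole_directions(geom_b)
  z_ref <- orientation_factor(da["Qy", ], db["Qy", ], e_ab)
  if (abs(z_ref) < 1e-10) {
    stop("Qy-Qy orientation factor vanishes; cannot anchor couplings",
         call. = FALSE)
  }
  lab <- states$label
  f <- sqrt(states$dipole_ratio_sq)
  J <- matrix(0, length(lab), length(lab), dimnames = list(lab, lab))
  for (m in seq_along(lab)) for (n in seq_along(lab)) {
    z <- orientation_factor(da[lab[m], ], db[lab[n], ], e_ab)
    J[m, n] <- J_QyQy * f[m] * f[n] * z / z_ref
  }
  class(J) <- c("coupling_matrix", class(J))
  J
}

#' Assemble the dimer Hamiltonian in the one-particle approximation
#'
#' The singly excited dimer basis is the union of the two monomer bases,
#' the de-excited partner being held in its vibrational ground state (OPA).
#' The Hamiltonian has block form `[H_A, V; t(V), H_B]` with
#' `V[i, j] = J[m_i, n_j] * FC_i * FC_j`: the electronic coupling between
#' the localized transitions is dressed by the Franck-Condon amplitudes of
#' the two excited-side vibronic basis states with respect to their ground
#' states (the de-excited side contributes its ground-state overlap, unity
#' in the OPA).  Since the vibronic-coupling mode is undisplaced, only
#' basis states without coupling-mode quanta couple excitonically.
#'
#' @param monomer_a,monomer_b [assemble_monomer()] objects (geometries must
#'   have distinct centers).
#' @param couplings A [scaled_couplings()] matrix (cm^-1), or `NULL` to
#'   compute it from the two geometries with the default anchor.
#' @param coupling_mask `"all"` or `"zero_zero_only"` (keep only couplings
#'   between basis states with no vibrational quanta on either side), or a
#'   function `f(basis_i, basis_j)` returning a logical mask.
#' @return Object of class `dimer_system`: `basis` (with `pigment` column),
#'   `H`, `mu`, `m`, `monomers`, `couplings`.
#' @export
assemble_dimer <- function(monomer_a, monomer_b, couplings = NULL,
                           coupling_mask = "all") {
  stopifnot(inherits(monomer_a, "vibronic_monomer"),
            inherits(monomer_b, "vibronic_monomer"))
  if (is.null(couplings)) {
    couplings <- scaled_couplings(monomer_a$geometry, monomer_b$geometry,
                                  monomer_a$params$states)
  }
  ba <- monomer_a$basis
  bb <- monomer_b$basis
  Ka <- nrow(ba); Kb <- nrow(bb)
  V <- couplings[ba$electronic, bb$electronic, drop = FALSE] *
    outer(ba$fc, bb$fc)
  mask <- build_coupling_mask(coupling_mask, ba, bb)
  V <- V * mask
  H <- rbind(cbind(monomer_a$H, V), cbind(t(V), monomer_b$H))
  basis <- rbind(cbind(pigment = 1L, ba), cbind(pigment = 2L, bb))
  class(basis) <- c("vibronic_basis", "data.frame")
  structure(list(basis = basis, H = H,
                 mu = rbind(monomer_a$mu, monomer_b$mu),
                 m = rbind(monomer_a$m, monomer_b$m),
                 monomers = list(monomer_a, monomer_b),
                 couplings = couplings, coupling_mask = coupling_mask),
            class = "dimer_system")
}

build_coupling_mask <- function(mask, ba, bb) {
  if (is.function(mask)) {
    out <- outer(seq_len(nrow(ba)), seq_len(nrow(bb)),
                 function(i, j) mask(ba[i, , drop = FALSE], bb[j, , drop = FALSE]))
    return(out * 1)
  }
  if (identical(mask, "all")) return(matrix(1, nrow(ba), nrow(bb)))
  if (identical(mask, "zero_zero_only")) {
    za <- ba$n_vc == 0L & ba$mode_quanta == 0L
    zb <- bb$n_vc == 0L & bb$mode_quanta == 0L
    return(outer(za, zb) * 1)
  }
  stop("unknown coupling mask: ", mask, call. = FALSE)
}

#' @export
print.dimer_system <- function(x, ...) {
  cat("Excitonically coupled dimer:", nrow(x$H), "one-particle basis states\n")
  cat(sprintf("  J(QyQy) = %.1f cm^-1; coupling mask: %s\n",
              x$couplings["Qy", "Qy"],
              if (is.function(x$coupling_mask)) "<function>" else x$coupling_mask))
  invisible(x)
}

#' Magnetic transition-dipole vectors
#'
#' For a localized transition on a pigment at position R with electric
#' transition dipole mu, the magnetic transition dipole is `m = i R x mu`
#' (proportionality constant set to one; the CD spectrum is reported in
#' relative units).  The returned vectors are the real factors `R x mu`;
#' the imaginary unit is implicit and rotational strengths are computed as
#' the real dot product `(R x mu) . mu_exc`.  The intrinsic pigment CD is
#' neglected.
#'
#' @param geometry A [pigment_geometry()].
#' @param electric_dipoles n x 3 matrix of electric transition-dipole
#'   vectors of basis states localized on this pigment.
#' @return n x 3 matrix of magnetic dipole vectors.
#' @export
magnetic_dipoles <- function(geometry, electric_dipoles) {
  stopifnot(inherits(geometry, "pigment_geometry"))
  ed <- rbind(electric_dipoles)
  cross3(matrix(geometry$center, nrow(ed), 3, byrow = TRUE), ed)
}

#' @rdname exciton_states
#' @export
exciton_states.dimer_system <- function(x, ...) {
  decompose_system(x$H, x$mu, x$m, pigment = x$basis$pigment, basis = x$basis)
}
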