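#' Franck-Condon amplitude of a displaced harmonic oscillator
#'
#' Overlap `<n|0~>` between the n-th oscillator eigenstate of an electronic
#' excited state and the vibrational ground state of the electronic ground
#' state, for a mode with Huang-Rhys factor S (equal frequencies, shifted
#' minimum).  The squared amplitude is the Poisson weight
#' `exp(-S) S^n / n!`; amplitudes are taken positive (only their squares
#' and symmetric products enter observables in this model).
#'
#' @param S Huang-Rhys factor (>= 0), scalar.
#' @param n Vibrational quantum number(s) (>= 0).
#' @return Amplitude(s) `sqrt(exp(-S) S^n / n!)`.
#' @export
franck_condon_amplitude <- function(S, n) {
  if (length(S) != 1 || S < 0) stop("`S` must be a scalar >= 0", call. = FALSE)
  if (any(n < 0)) stop("`n` must be >= 0", call. = FALSE)
  n <- as.integer(n)
  # S = 0: amplitude is delta_{n,0}; 0^0 handled explicitly
  sqrt(exp(-S) * S^n / factorial(n)) * ifelse(S == 0 & n > 0, 0, 1)
}

#' Enumerate the truncated vibronic basis of a monomer
#'
#' One basis state per combination of electronic state, vibronic-coupling-mode
#' quantum number `n_vc` (0..max_quanta) and intramolecular excitation
#' (`mode_index = 0`: all intramolecular modes in their ground state;
#' `mode_index = i > 0`: mode i excited to its first eigenstate).  Purely
#' electronic states (By, Bx) carry a single basis state.  Per basis state
#' the table carries the diagonal energy (relative to the Qy 0-0 line), the
#' Franck-Condon amplitude of the transition from the global ground state,
#' and the transition-dipole amplitude `sqrt(f) * FC`.
#'
#' @param params A [monomer_params()].
#' @return Data frame of class `vibronic_basis`, deterministically ordered by
#'   electronic state (order of `params$states`), then `mode_index`, then
#'   `n_vc`.
#' @export
build_basis <- function(params) {
  stopifnot(inherits(params, "monomer_params"))
  st <- params$states
  modes <- params$modes
  nm <- nrow(modes)
  nvc_max <- params$vc$max_quanta
  rows <- list()
  for (k in seq_len(nrow(st))) {
    lab <- st$label[k]
    if (!st$has_vibrations[k]) {
      rows[[length(rows) + 1L]] <- data.frame(
        electronic = lab, n_vc = 0L, mode_index = 0L, mode_quanta = 0L,
        energy = st$energy_offset[k], stringsAsFactors = FALSE)
      next
    }
    for (mi in 0:nm) {
      for (n in 0:nvc_max) {
        e <- st$energy_offset[k] + n * params$vc$frequency +
          if (mi > 0) modes$frequency[mi] else 0
        rows[[length(rows) + 1L]] <- data.frame(
          electronic = lab, n_vc = as.integer(n), mode_index = as.integer(mi),
          mode_quanta = as.integer(mi > 0), energy = e, stringsAsFactors = FALSE)
      }
    }
  }
  basis <- do.call(rbind, rows)
  # Franck-Condon amplitude from the global vibrational ground state:
  # the VC mode is undisplaced (amplitude delta_{n_vc,0}); the intramolecular
  # product contributes exp(-sum(S)/2) times sqrt(S_i) if mode i is excited.
  fc <- numeric(nrow(basis))
  for (r in seq_len(nrow(basis))) {
    lab <- basis$electronic[r]
    if (!st$has_vibrations[st$label == lab]) { fc[r] <- 1; next }
    if (basis$n_vc[r] > 0) { fc[r] <- 0; next }
    S <- modes[[paste0("S_", lab)]]
    amp <- exp(-sum(S) / 2)
    if (basis$mode_index[r] > 0) amp <- amp * sqrt(S[basis$mode_index[r]])
    fc[r] <- amp
  }
  basis$fc <- fc
  basis$mu_amp <- fc * sqrt(st$dipole_ratio_sq[match(basis$electronic, st$label)])
  class(basis) <- c("vibronic_basis", "data.frame")
  basis
}

#' Assemble the vibronic monomer Hamiltonian
#'
#' Builds the dense symmetric Hamiltonian in the truncated vibronic basis.
#' Diagonal entries are the basis-state energies relative to the Qy 0-0
#' line.  The vibronic coupling, linear in the coupling-mode coordinate,
#' connects `|Qy, n_vc, v>` with `|Qx, n_vc +/- 1, v>` (identical
#' intramolecular excitation v on both sides) with matrix element
#' `alpha~ * sqrt(max(n_vc, n_vc') / 2)`, the harmonic-ladder rule
#' `<n|q|n+1> = sqrt((n+1) / (2 omega))` expressed through the scaled
#' coupling constant `alpha~ = alpha / sqrt(omega_VC)`.
#'
#' @param params A [monomer_params()].
#' @param geometry A `pigment_geometry` supplying dipole directions and the
#'   pigment center; defaults to a standard frame at the origin.
#' @return Object of class `vibronic_monomer`: list with `basis`, `H`,
#'   `mu` (basis-state electric transition-dipole vectors, rows), `m`
#'   (magnetic dipole vectors, `R x mu`, imaginary prefactor implicit),
#'   `params`, `geometry`.
#' @export
assemble_monomer <- function(params, geometry = default_pigment_geometry()) {
  stopifnot(inherits(params, "monomer_params"))
  basis <- build_basis(params)
  K <- nrow(basis)
  H <- matrix(0, K, K)
  diag(H) <- basis$energy
  at <- params$vc$coupling_scaled
  if (at != 0 && all(c("Qy", "Qx") %in% params$states$label)) {
    vib <- params$states$label[params$states$vibronically_coupled]
    iy <- which(basis$electronic == "Qy")
    ix <- which(basis$electronic == "Qx")
    for (a in iy) for (b in ix) {
      if (basis$mode_index[a] == basis$mode_index[b] &&
          abs(basis$n_vc[a] - basis$n_vc[b]) == 1L) {
        el <- at * sqrt(max(basis$n_vc[a], basis$n_vc[b]) / 2)
        H[a, b] <- H[b, a] <- el
      }
    }
  }
  dirs <- dipole_directions(geometry)
  mu <- dirs[basis$electronic, , drop = FALSE] * basis$mu_amp
  m <- cross3(matrix(geometry$center, K, 3, byrow = TRUE), mu)
  dimnames(mu) <- dimnames(m) <- NULL
  structure(list(basis = basis, H = H, mu = mu, m = m,
                 params = params, geometry = geometry),
            class = "vibronic_monomer")
}

#' @export
print.vibronic_monomer <- function(x, ...) {
  cat("Vibronic monomer Hamiltonian:", nrow(x$H), "basis states\n")
  cat("  states:", paste(unique(x$basis$electronic), collapse = ", "), "\n")
  cat(sprintf("  total dipole strength (basis): %.4f |mu_Qy|^2\n",
              sum(x$basis$mu_amp^2)))
  invisible(x)
}

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Exciton decomposition of a vibronic system
#'
#' Diagonalizes the system Hamiltonian and transforms transition dipoles to
#' the exciton basis: `mu_exc[alpha] = sum_i A[i, alpha] mu[i]` and
#' analogously for the magnetic dipoles.  The bath weights
#' `gamma[alpha, beta] = sum_a <alpha|P_a|beta>^2` (P_a projects on the
#' basis states of pigment a) follow from the site-diagonal system-bath
#' coupling; `gamma[alpha, alpha]` is the inverse participation ratio of
#' state alpha over pigments.
#'
#' @param x A `vibronic_monomer` or `dimer_system`.
#' @param ... Unused.
#' @return Object of class `exciton_decomposition`: `energies` (ascending,
#'   cm^-1 relative to the Qy 0-0 reference), `A` (orthogonal coefficient
#'   matrix, columns = exciton states), `mu_exc`, `m_exc` (K x 3), `rot`
#'   (rotational strengths `mu_exc . m_exc`), `gamma`, `basis`, `pigment`.
#' @export
exciton_states <- function(x, ...) UseMethod("exciton_states")

#' @rdname exciton_states
#' @export
exciton_states.vibronic_monomer <- function(x, ...) {
  decompose_system(x$H, x$mu, x$m, pigment = rep(1L, nrow(x$H)), basis = x$basis)
}

decompose_system <- function(H, mu, m, pigment, basis) {
  if (any(!is.finite(H))) stop("Hamiltonian contains non-finite entries", call. = FALSE)
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  A <- eig$vectors[, ord, drop = FALSE]
  energies <- eig$values[ord]
  mu_exc <- crossprod(A, mu)
  m_exc <- crossprod(A, m)
  K <- length(energies)
  gamma <- matrix(0, K, K)
  for (p in unique(pigment)) {
    Sp <- crossprod(A[pigment == p, , drop = FALSE])
    gamma <- gamma + Sp^2
  }
  structure(list(energies = energies, A = A, mu_exc = mu_exc, m_exc = m_exc,
                 rot = rowSums(mu_exc * m_exc), gamma = gamma,
                 basis = basis, pigment = pigment),
            class = "exciton_decomposition")
}

#' @export
print.exciton_decomposition <- function(x, ...) {
  K <- length(x$energies)
  cat("Exciton decomposition:", K, "states,",
      length(unique(x$pigment)), "pigment(s)\n")
  ds <- rowSums(x$mu_exc^2)
  top <- order(ds, decreasing = TRUE)[seq_len(min(5, K))]
  cat("  brightest states (energy cm^-1 / dipole strength / rot. strength):\n")
  for (a in top) {
    cat(sprintf("    %9.1f  %8.4f  %+8.4f\n", x$energies[a], ds[a], x$rot[a]))
  }
  invisible(x)
}

#' @export
summary.exciton_decomposition <- function(object, n = 10, ...) {
  ds <- rowSums(object$mu_exc^2)
  df <- data.frame(energy = object$energies, dipole_strength = ds,
                   rotational_strength = object$rot,
                   participation = diag(object$gamma))
  df[seq_len(min(n, nrow(df))), ]
}

#' Effective Huang-Rhys factor of the vibronic coupling mode
#'
#' Although the coupling mode is not displaced in any electronic state, the
#' off-diagonal vibronic coupling induces Franck-Condon-like activity in its
#' progression.  This diagnostic infers an effective Huang-Rhys factor from
#' the intensity ratio of the 0-1 to the 0-0 member of the coupling-mode
#' progression on the lowest adiabatic state: the 0-1 intensity is summed
#' over eigenstates whose dominant basis component is `|Qy, n_vc = 1>`
#' without intramolecular excitation, and divided by the intensity of the
#' lowest eigenstate (for a Poisson progression this ratio equals S).
#' Reported as a diagnostic only; nothing downstream consumes it.
#'
#' @param dec An [exciton_states()] decomposition of a monomer.
#' @return Dimensionless effective Huang-Rhys factor.
#' @export
effective_vc_huang_rhys <- function(dec) {
  stopifnot(inherits(dec, "exciton_decomposition"))
  ds <- rowSums(dec$mu_exc^2)
  i00 <- ds[1]
  if (i00 <= 0) stop("lowest eigenstate carries no intensity", call. = FALSE)
  dom <- apply(dec$A^2, 2, which.max)
  sel <- dec$basis$electronic[dom] == "Qy" & dec$basis$n_vc[dom] == 1L &
    dec$basis$mode_quanta[dom] == 0L
  sum(ds[sel]) / i00
}
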