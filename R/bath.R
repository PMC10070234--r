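#' Super-Ohmic bath spectral density
#'
#' `J(w) = sum_k s_k w^3 / (7! * 2 * w_k^4) * exp(-sqrt(w / w_k))`.
#' With this normalization the integral of J equals `s1 + s2` (the bath
#' Huang-Rhys factor) and the first moment equals `72 (s1 w1 + s2 w2)`
#' (the bath reorganization energy lambda).
#'
#' @param omega Frequencies in cm^-1 (>= 0).
#' @param bath A [bath_params()].
#' @return Spectral density values (units 1/cm^-1).
#' @export
spectral_density <- function(omega, bath = bath_params()) {
  if (any(omega < 0)) {
    stop("`omega` must be >= 0 (the signed extension lives in the bath ",
         "correlation function)", call. = FALSE)
  }
  term <- function(s, wk) s * omega^3 / (factorial(7) * 2 * wk^4) *
    exp(-sqrt(omega / wk))
  term(bath$s1, bath$omega1) + term(bath$s2, bath$omega2)
}

#' Bath Huang-Rhys factor and reorganization energy
#'
#' Closed-form moments of the spectral density:
#' `S_bath = s1 + s2` and `lambda = 72 (s1 w1 + s2 w2)` in cm^-1.
#'
#' @param bath A [bath_params()].
#' @return Named list with `huang_rhys` and `lambda`.
#' @export
bath_moments <- function(bath = bath_params()) {
  list(huang_rhys = bath$s1 + bath$s2,
       lambda = 72 * (bath$s1 * bath$omega1 + bath$s2 * bath$omega2))
}

bose_einstein <- function(omega, temperature) {
  1 / expm1(omega / (.kB_cm * temperature))
}

#' Real part of the Fourier-transformed bath correlation function
#'
#' `Re C~(w) = pi w^2 [1 + n(w)] [J(w) - J(-w)]` with the Bose-Einstein
#' occupation n and `J(w) = 0` for `w < 0`.  Satisfies detailed balance
#' `Re C~(-w) = exp(-w / kT) Re C~(w)`; rates of Eq.-type
#' `Gamma = 2 gamma Re C~(w_ab)` come out in cm^-1 and convert to fs via
#' `1 / (2 pi c Gamma)`.
#'
#' @param omega Signed frequencies in cm^-1 (positive = downhill).
#' @param bath A [bath_params()].
#' @param temperature Temperature in K; defaults to the bath temperature.
#' @return `Re C~(omega)` in cm^-1.
#' @export
bath_correlation_re <- function(omega, bath = bath_params(),
                                temperature = bath$temperature) {
  if (temperature <= 0) stop("`temperature` must be > 0", call. = FALSE)
  aw <- abs(omega)
  J <- spectral_density(aw, bath)
  out <- numeric(length(omega))
  pos <- omega > 0
  neg <- omega < 0
  out[pos] <- pi * aw[pos]^2 * (1 + bose_einstein(aw[pos], temperature)) * J[pos]
  out[neg] <- pi * aw[neg]^2 * bose_einstein(aw[neg], temperature) * J[neg]
  out  # omega = 0: J ~ w^3 kills the integrand, Re C~(0) = 0
}

#' Imaginary part of the Fourier-transformed bath correlation function
#'
#' Obtained from the real part by the principal-value (Kramers-Kronig)
#' transform `Im C~(w) = (1/pi) P int Re C~(w') / (w - w') dw'`, evaluated
#' once on a uniform grid by singularity subtraction and interpolated.
#'
#' @inheritParams bath_correlation_re
#' @return `Im C~(omega)` in cm^-1.
#' @export
bath_correlation_im <- function(omega, bath = bath_params(),
                                temperature = bath$temperature) {
  tab <- bath_correlation_im_table(bath, temperature)
  stats::approx(tab$omega, tab$im, xout = omega, rule = 2)$y
}

# cached principal-value transform on a uniform grid
bath_correlation_im_table <- local({
  cache <- new.env(parent = emptyenv())
  function(bath, temperature, L = 4000, n = 4001) {
    key <- paste(bath$s1, bath$s2, bath$omega1, bath$omega2, temperature,
                 L, n, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    wg <- seq(-L, L, length.out = n)
    dw <- wg[2] - wg[1]
    re <- bath_correlation_re(wg, bath, temperature)
    im <- numeric(n)
    for (k in seq_len(n)) {
      w <- wg[k]
      f <- (re - re[k]) / (w - wg)
      f[k] <- 0  # removable: derivative term is dropped with the symmetric grid
      # P int re(w')/(w - w') dw' = int (re(w') - re(w))/(w - w') dw'
      #                             + re(w) * log((L + w)/(L - w))
      edge <- if (abs(w) < L) re[k] * log((L + w) / (L - w)) else 0
      im[k] <- (sum(f) - f[1] / 2 - f[n] / 2) * dw + edge
    }
    out <- list(omega = wg, im = im / pi)
    cache[[key]] <- out
    out
  }
})

#' Line-broadening function of the bath
#'
#' `g(t) = int_0^inf dw J(w) [ (1 + n(w)) exp(-2i pi c w t)
#'                             + n(w) exp(+2i pi c w t) ]`,
#' the per-unit-coupling lineshape exponent; exciton state alpha uses
#' `G_aa(t) = gamma_aaaa * g(t)`.  `g(0)` is real and equals the
#' coth-weighted bath Huang-Rhys factor (at T = 0 it reduces to S_bath, the
#' Franck-Condon limit `exp(-G(0)) = exp(-S_bath)`).
#'
#' @param t_fs Time grid in fs.
#' @param bath A [bath_params()].
#' @param temperature Temperature in K (0 allowed here).
#' @param omega_max,n_omega Quadrature grid for the frequency integral.
#' @return Complex vector `g(t)` on the time grid.
#' @export
line_broadening_g <- function(t_fs, bath = bath_params(),
                              temperature = bath$temperature,
                              omega_max = 2500, n_omega = 5001) {
  key <- paste(bath$s1, bath$s2, bath$omega1, bath$omega2, temperature,
               omega_max, n_omega, length(t_fs), t_fs[1],
               t_fs[length(t_fs)], sep = "_")
  hit <- .g_cache[[key]]
  if (!is.null(hit)) return(hit)
  wg <- seq(0, omega_max, length.out = n_omega)
  dw <- wg[2] - wg[1]
  J <- spectral_density(wg, bath)
  nw <- if (temperature > 0) {
    c(0, bose_einstein(wg[-1], temperature))  # n * J -> 0 as w -> 0 (J ~ w^3)
  } else rep(0, length(wg))
  trap <- rep(dw, length(wg)); trap[1] <- trap[length(wg)] <- dw / 2
  a_down <- J * (1 + nw) * trap
  a_up <- J * nw * trap
  out <- complex(length(t_fs))
  chunk <- 512L
  for (i0 in seq(1L, length(t_fs), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(t_fs))
    ph <- outer(t_fs[idx], wg) * (2 * pi * .c_cm_fs)
    out[idx] <- exp(-1i * ph) %*% a_down + exp(1i * ph) %*% a_up
  }
  .g_cache[[key]] <- out
  out
}

.g_cache <- new.env(parent = emptyenv())

#' Renormalized energies, lifetimes and lifetime broadening
#'
#' For every exciton state alpha computes the renormalized transition
#' energy `w~_a0 = w_a0 - gamma_aaaa lambda
#' + sum_{b != a} gamma_abba Im C~(w_ab)`, the inter-exciton relaxation
#' rates `Gamma_ltb[a, b] = 2 gamma_abba Re C~(w_ab)` and the dephasing
#' time `tau_a = [ (1/2) sum_b Gamma_ltb[a, b] ]^-1` (in fs, capped at
#' `bath$tau_max_fs`).
#'
#' @param decomposition An [exciton_states()] decomposition.
#' @param bath A [bath_params()].
#' @param temperature Temperature in K.
#' @return Object of class `lineshape_terms`: `omega_renorm` (cm^-1),
#'   `tau_fs`, `Gamma` (matrix, cm^-1), `lambda`, plus the inputs.
#' @export
lifetimes <- function(decomposition, bath = bath_params(),
                      temperature = bath$temperature) {
  stopifnot(inherits(decomposition, "exciton_decomposition"))
  lam <- bath_moments(bath)$lambda
  w <- decomposition$energies
  dw <- outer(w, w, "-")
  gam <- decomposition$gamma
  Gam <- 2 * gam * matrix(bath_correlation_re(as.numeric(dw), bath, temperature),
                          nrow(dw), ncol(dw))
  imC <- matrix(bath_correlation_im(as.numeric(dw), bath, temperature),
                nrow(dw), ncol(dw))
  shift <- rowSums(gam * imC) - diag(gam) * diag(imC)
  omega_renorm <- w - diag(gam) * lam + shift
  half_rate <- pmax(rowSums(Gam) / 2, 1 / (2 * pi * .c_cm_fs * bath$tau_max_fs))
  structure(list(omega_renorm = omega_renorm, tau_fs = rate_to_fs(half_rate),
                 Gamma = Gam, lambda = lam, bath = bath,
                 temperature = temperature),
            class = "lineshape_terms")
}
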