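#' Propagation time / frequency grid
#'
#' Uniform time grid for the correlation functions and the matching FFT
#' frequency axis.  With the defaults (4096 points, 1 fs) the Nyquist
#' frequency is about 16700 cm^-1 -- more than twice the highest transition
#' of interest relative to the Qy 0-0 line -- and the frequency resolution
#' is about 8 cm^-1.
#'
#' @param n_t Number of time points (a power of two keeps the FFT fast).
#' @param dt_fs Time step in fs.
#' @return List of class `spectrum_grid` with `t_fs`, `freq` (sorted signed
#'   wavenumber axis) and bookkeeping fields.
#' @export
spectrum_grid <- function(n_t = 4096, dt_fs = 1) {
  stopifnot(n_t > 1, dt_fs > 0)
  t_fs <- (seq_len(n_t) - 1) * dt_fs
  k <- seq_len(n_t) - 1
  freq_raw <- k / (n_t * dt_fs * .c_cm_fs)
  freq_raw[k >= n_t / 2] <- freq_raw[k >= n_t / 2] - 1 / (dt_fs * .c_cm_fs)
  ord <- order(freq_raw)
  structure(list(t_fs = t_fs, n_t = n_t, dt_fs = dt_fs,
                 freq = freq_raw[ord], fft_order = ord),
            class = "spectrum_grid")
}

#' Correlation functions of absorption and circular dichroism
#'
#' Assembles `C_abs(t) = (1/3) sum_a |mu_exc,a|^2 C_a(t)` and
#' `C_CD(t) = (1/3) sum_a i R_a C_a(t)` with the per-state factor
#' `C_a(t) = exp(-2i pi c w~_a t) exp(G_aa(t) - G_aa(0)) exp(-t / tau_a)`,
#' `G_aa = gamma_aaaa g(t)`, and the rotational strength
#' `R_a = (R x mu)_exc,a . mu_exc,a`.  The factor `i` is the imaginary unit
#' of the magnetic transition dipole `m = i R x mu`; together with the
#' imaginary-part selection of the CD Fourier transform it yields absorptive
#' rotational-strength lobes.  The global factor 1/3 is the orientational
#' average.
#'
#' @param decomposition An [exciton_states()] decomposition.
#' @param lineshape A [lifetimes()] object for the same decomposition.
#' @param grid A [spectrum_grid()].
#' @param g_t Optional precomputed [line_broadening_g()] trajectory on
#'   `grid$t_fs` (it depends only on bath and temperature, so callers
#'   looping over disorder realizations should compute it once).
#' @return List with complex vectors `C_abs` and `C_cd` on the time grid.
#' @export
correlation_functions <- function(decomposition, lineshape, grid,
                                  g_t = NULL) {
  stopifnot(inherits(decomposition, "exciton_decomposition"),
            inherits(lineshape, "lineshape_terms"),
            inherits(grid, "spectrum_grid"))
  if (length(lineshape$omega_renorm) != length(decomposition$energies)) {
    stop("decomposition and lineshape sizes differ", call. = FALSE)
  }
  if (is.null(g_t)) {
    g_t <- line_broadening_g(grid$t_fs, lineshape$bath, lineshape$temperature)
  } else if (length(g_t) != grid$n_t) {
    stop("`g_t` does not match the time grid", call. = FALSE)
  }
  w_abs <- rowSums(decomposition$mu_exc^2) / 3
  w_cd <- 1i * decomposition$rot / 3  # m = i R x mu carries the imaginary unit
  keep <- w_abs > 1e-12 * max(w_abs) | abs(w_cd) > 0
  gam <- diag(decomposition$gamma)[keep]
  arg <- outer(grid$t_fs, -2i * pi * .c_cm_fs * lineshape$omega_renorm[keep] -
                 1 / lineshape$tau_fs[keep]) +
    outer(g_t - g_t[1], gam)
  M <- exp(arg)
  list(C_abs = as.vector(M %*% w_abs[keep]),
       C_cd = as.vector(M %*% w_cd[keep]))
}

#' One-sided Fourier transform of a correlation function
#'
#' `sigma_abs(w) = Re int_0^inf dt exp(2i pi c w t) C(t)` (absorption) or
#' the imaginary part (CD), discretized with trapezoid end-point weights on
#' the time grid.  With the adopted sign convention higher transition
#' energies appear at higher wavenumber.
#'
#' @param C_t Complex correlation function on `grid$t_fs`.
#' @param grid A [spectrum_grid()].
#' @param kind `"abs"` (real part) or `"cd"` (imaginary part).
#' @return Numeric spectrum on `grid$freq`.
#' @export
fourier_spectrum <- function(C_t, grid, kind = c("abs", "cd")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "spectrum_grid"), length(C_t) == grid$n_t)
  tail <- abs(C_t[grid$n_t])
  if (tail > 1e-4 * max(abs(C_t))) {
    warning("correlation function has not decayed at the end of the time ",
            "window (tail ", format(tail / max(abs(C_t)), digits = 2),
            " of max); increase n_t or reduce tau_max", call. = FALSE)
  }
  S <- (stats::fft(C_t, inverse = TRUE) - C_t[1] / 2) * grid$dt_fs
  S <- S[grid$fft_order]
  if (kind == "abs") Re(S) else Im(S)
}

new_spectrum_result <- function(freq, absorption, cd, meta) {
  structure(list(freq = freq, absorption = absorption, cd = cd, meta = meta),
            class = "spectrum_result")
}

#' Homogeneous absorption and CD spectrum of a vibronic system
#'
#' Diagonalizes the system, applies the bath lineshape theory and Fourier
#' transforms to a [spectrum_result].
#'
#' @param system A `vibronic_monomer` or `dimer_system`.
#' @param bath A [bath_params()].
#' @param grid A [spectrum_grid()].
#' @param g_t Optional precomputed [line_broadening_g()] trajectory.
#' @return Object of class `spectrum_result` with fields `freq` (cm^-1
#'   relative to the Qy 0-0 reference), `absorption`, `cd`, `meta`.
#' @export
homogeneous_spectrum <- function(system, bath = bath_params(),
                                 grid = spectrum_grid(), g_t = NULL) {
  dec <- exciton_states(system)
  ls <- lifetimes(dec, bath)
  cf <- correlation_functions(dec, ls, grid, g_t = g_t)
  new_spectrum_result(grid$freq,
                      fourier_spectrum(cf$C_abs, grid, "abs"),
                      fourier_spectrum(cf$C_cd, grid, "cd"),
                      meta = list(kind = class(system)[1],
                                  temperature = bath$temperature,
                                  n_samples = 0L, disorder = NULL))
}

site_shift_table <- function(disorder, n_pigments) {
  # one row per realization-independent draw: matrix [pigment, state]
  function() {
    sig <- disorder$fwhm / (2 * sqrt(2 * log(2)))
    sh <- matrix(stats::rnorm(4 * n_pigments, 0, rep(sig, each = n_pigments)),
                 n_pigments, 4, dimnames = list(NULL, names(sig)))
    if (disorder$correlated_qx && sig[["Qy"]] > 0) {
      sh[, "Qx"] <- sh[, "Qy"] * sig[["Qx"]] / sig[["Qy"]]
    }
    sh
  }
}

#' Monte-Carlo average over Gaussian site-energy disorder
#'
#' Adds independent Gaussian shifts to the local 0-0 energies of every
#' pigment and electronic state (the diagonal of the Hamiltonian before
#' mixing), re-diagonalizes per realization -- site-energy disorder thereby
#' localizes exciton states, the mechanism suppressing high-energy CD --
#' and averages the correlation functions.  Deterministic for a fixed
#' `disorder$seed`; the RNG state of the session is restored on exit.
#'
#' @param system A `vibronic_monomer` or `dimer_system`.
#' @param disorder A [disorder_model()].
#' @param bath A [bath_params()].
#' @param grid A [spectrum_grid()].
#' @return A `spectrum_result` (disorder-averaged).
#' @export
disorder_average <- function(system, disorder, bath = bath_params(),
                             grid = spectrum_grid()) {
  stopifnot(inherits(disorder, "disorder_model"))
  if (disorder$n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(disorder$seed)
  pig <- if (inherits(system, "dimer_system")) system$basis$pigment
         else rep(1L, nrow(system$H))
  basis <- if (inherits(system, "dimer_system")) system$basis else system$basis
  n_pig <- length(unique(pig))
  draw <- site_shift_table(disorder, n_pig)
  g_t <- line_broadening_g(grid$t_fs, bath, bath$temperature)
  Ca <- Cc <- complex(grid$n_t)
  for (r in seq_len(disorder$n_samples)) {
    sh <- draw()
    H <- system$H
    diag(H) <- diag(H) + sh[cbind(pig, match(basis$electronic, colnames(sh)))]
    dec <- decompose_system(H, system$mu, system$m, pig, basis)
    ls <- lifetimes(dec, bath)
    cf <- correlation_functions(dec, ls, grid, g_t = g_t)
    Ca <- Ca + cf$C_abs
    Cc <- Cc + cf$C_cd
  }
  Ca <- Ca / disorder$n_samples
  Cc <- Cc / disorder$n_samples
  new_spectrum_result(grid$freq,
                      fourier_spectrum(Ca, grid, "abs"),
                      fourier_spectrum(Cc, grid, "cd"),
                      meta = list(kind = class(system)[1],
                                  temperature = bath$temperature,
                                  n_samples = disorder$n_samples,
                                  seed = disorder$seed,
                                  disorder_fwhm = disorder$fwhm))
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("Spectrum (", x$meta$kind, ", T = ", x$meta$temperature, " K, ",
      if (x$meta$n_samples > 0) paste0(x$meta$n_samples, " disorder samples")
      else "homogeneous", ")\n", sep = "")
  cat(sprintf("  frequency range: %.0f .. %.0f cm^-1 (relative to Qy 0-0)\n",
              min(x$freq), max(x$freq)))
  cat(sprintf("  absorption integral: %.4g; CD integral: %.2g (sum rule)\n",
              spectrum_integral(x, "absorption"), spectrum_integral(x, "cd")))
  invisible(x)
}

#' @export
as.data.frame.spectrum_result <- function(x, ...) {
  data.frame(wavenumber = x$freq, absorption = x$absorption, cd = x$cd)
}

#' @export
plot.spectrum_result <- function(x, xlim = c(-1000, 4000), absolute = FALSE,
                                 qy_energy = NULL, ...) {
  f <- x$freq
  xlab <- expression(paste(nu - nu["Qy,0-0"], " [", cm^-1, "]"))
  if (absolute) {
    if (is.null(qy_energy)) stop("`qy_energy` needed for an absolute axis")
    f <- f + qy_energy
    xlim <- xlim + qy_energy
    xlab <- expression(paste(nu, " [", cm^-1, "]"))
  }
  sel <- f >= xlim[1] & f <= xlim[2]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(f[sel], x$absorption[sel], type = "l", xlab = xlab,
                 ylab = "absorption [a.u.]", ...)
  graphics::plot(f[sel], x$cd[sel], type = "l", xlab = xlab,
                 ylab = "CD [rel. units]", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Integral of a spectrum over its frequency axis
#'
#' @param spectrum A `spectrum_result`.
#' @param what `"absorption"`, `"cd"` or `"abs_cd"` (integral of |CD|).
#' @param range Optional frequency window `c(lo, hi)` in cm^-1.
#' @return Trapezoid integral over the (windowed) axis.
#' @export
spectrum_integral <- function(spectrum, what = c("absorption", "cd", "abs_cd"),
                              range = NULL) {
  what <- match.arg(what)
  y <- switch(what, absorption = spectrum$absorption, cd = spectrum$cd,
              abs_cd = abs(spectrum$cd))
  f <- spectrum$freq
  if (!is.null(range)) {
    sel <- f >= range[1] & f <= range[2]
    f <- f[sel]; y <- y[sel]
  }
  sum(diff(f) * (y[-1] + y[-length(y)]) / 2)
}

#' Write a spectrum to TSV with a JSON sidecar
#'
#' @param spectrum A `spectrum_result`.
#' @param path Output TSV path (`wavenumber_cm-1`, `absorption`, `cd`); a
#'   sidecar `<path>.json` records the metadata.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- as.data.frame(spectrum)
  names(df) <- c("wavenumber_cm-1", "absorption", "cd")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(spectrum$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
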