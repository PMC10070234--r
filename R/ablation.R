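#' Build a monomer or dimer system for a named model variant
#'
#' The step-wise model variants used throughout the package's analysis:
#' \describe{
#'   \item{`electronic`}{Qy only, no intramolecular vibrations, no vibronic
#'     coupling -- a single electronic transition dressed by the bath.}
#'   \item{`vibrations`}{Qy only with its intramolecular Franck-Condon
#'     progression.}
#'   \item{`qx`}{Qy and Qx with vibrations, vibronic coupling off.}
#'   \item{`vibronic`}{Qy and Qx with vibrations and vibronic coupling.}
#'   \item{`full`}{additionally the purely electronic By and Bx states.}
#'   \item{`zero_zero`}{as `full`, but excitonic coupling restricted to
#'     basis states without vibrational quanta (dimer only).}
#' }
#'
#' @param config A [default_config()]-style `run_config`.
#' @param kind `"monomer"` or `"dimer"`.
#' @param variant One of the variant names above.
#' @return A `vibronic_monomer` or `dimer_system`.
#' @export
build_system <- function(config, kind = c("dimer", "monomer"),
                         variant = "full") {
  kind <- match.arg(kind)
  known <- c("electronic", "vibrations", "qx", "vibronic", "full", "zero_zero")
  if (!variant %in% known) {
    stop("unknown model variant: ", variant, call. = FALSE)
  }
  if (variant == "zero_zero" && kind == "monomer") {
    stop("variant `zero_zero` restricts excitonic coupling and only applies ",
         "to the dimer", call. = FALSE)
  }
  cfg <- config
  include <- switch(variant,
                    electronic = "Qy", vibrations = "Qy",
                    qx = c("Qy", "Qx"), vibronic = c("Qy", "Qx"),
                    c("Qy", "Qx", "By", "Bx"))
  if (variant %in% c("electronic", "vibrations", "qx")) {
    cfg$vc_mode$coupling_scaled <- 0
  }
  if (variant == "electronic") {
    cfg$modes$frequency <- numeric()
    cfg$modes$S_Qy <- numeric()
    cfg$modes$qx_rescale_indices <- integer()
    cfg$vc_mode$max_quanta <- 0
  }
  params <- config_monomer_params(cfg, states_include = include)
  geom <- config_geometry(cfg)
  if (kind == "monomer") {
    return(assemble_monomer(params, geometry = geom[[1]]))
  }
  mon_a <- assemble_monomer(params, geometry = geom[[1]])
  mon_b <- assemble_monomer(params, geometry = geom[[2]])
  J <- scaled_couplings(geom[[1]], geom[[2]], params$states,
                        J_QyQy = cfg$coupling$J_QyQy)
  mask <- if (variant == "zero_zero") "zero_zero_only" else cfg$coupling$mask
  assemble_dimer(mon_a, mon_b, couplings = J, coupling_mask = mask)
}

#' Run the step-wise model ablation suite
#'
#' Computes absorption and CD spectra for a sequence of model variants
#' (see [build_system()]), homogeneous or disorder-averaged.
#'
#' @param config A `run_config`.
#' @param kind `"monomer"` or `"dimer"`.
#' @param variants Character vector of variant names.
#' @param inhomogeneous If `TRUE`, average over site-energy disorder with
#'   the configured model; otherwise homogeneous spectra.
#' @return Named list of `spectrum_result` objects (class
#'   `ablation_suite`).
#' @export
ablation_suite <- function(config, kind = c("dimer", "monomer"),
                           variants = NULL, inhomogeneous = FALSE) {
  kind <- match.arg(kind)
  if (is.null(variants)) {
    variants <- c("electronic", "vibrations", "qx", "vibronic", "full")
    if (kind == "dimer") variants <- c(variants, "zero_zero")
  }
  grid <- config_grid(config)
  bath <- config_bath(config)
  g_t <- line_broadening_g(grid$t_fs, bath, bath$temperature)
  out <- list()
  for (v in variants) {
    sys <- build_system(config, kind, v)
    out[[v]] <- if (inhomogeneous) {
      disorder_average(sys, config_disorder(config), bath, grid)
    } else {
      homogeneous_spectrum(sys, bath, grid, g_t = g_t)
    }
    out[[v]]$meta$variant <- v
  }
  class(out) <- c("ablation_suite", "list")
  out
}

#' Rescale CD spectra to a common positive peak amplitude
#'
#' For comparisons across model variants, each CD spectrum is rescaled so
#' that its maximum positive peak inside `region` has amplitude one.
#'
#' @param spectra A list of `spectrum_result` objects (e.g. an
#'   [ablation_suite()]).
#' @param region Frequency window searched for the positive peak.
#' @return The list with rescaled `cd` components (absorption untouched,
#'   scale factor recorded in `meta$cd_scale`).
#' @export
rescale_cd_to_positive_peak <- function(spectra, region = c(-1000, 1000)) {
  lapply(spectra, function(s) {
    sel <- s$freq >= region[1] & s$freq <= region[2]
    pk <- max(s$cd[sel])
    if (pk <= 0) stop("no positive CD peak in the reference region",
                      call. = FALSE)
    s$cd <- s$cd / pk
    s$meta$cd_scale <- 1 / pk
    s
  })
}
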