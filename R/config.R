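#' Default run configuration
#'
#' A run configuration is a plain nested list with sections `states`,
#' `modes`, `vc_mode`, `bath`, `disorder`, `coupling`, `geometry` and
#' `grid`, all energies in cm^-1, angles in degrees, distances in Angstrom.
#' Two presets ship: `"ether"` (chlorophyll a monomer in diethyl ether,
#' Qy 0-0 at 14910 cm^-1, inhomogeneous FWHM 240/720 cm^-1 for Qy/Qx) and
#' `"wscp"` (the strongly coupled WSCP dimer, Qy 0-0 at 14940 cm^-1, FWHM
#' 170/340 cm^-1).  Soret-band disorder (FWHM 1800 cm^-1) applies whenever
#' the B states are included.
#'
#' @param preset `"wscp"` or `"ether"`.
#' @return Nested configuration list of class `run_config`.
#' @export
default_config <- function(preset = c("wscp", "ether")) {
  preset <- match.arg(preset)
  fwhm <- if (preset == "wscp") list(Qy = 170, Qx = 340, By = 1800, Bx = 1800)
          else list(Qy = 240, Qx = 720, By = 1800, Bx = 1800)
  cfg <- list(
    preset = preset,
    qy_energy_absolute = if (preset == "wscp") 14940 else 14910,
    states = list(include = c("Qy", "Qx", "By", "Bx"),
                  dE_QxQy = 1640, dE_ByQy = 7570, dE_BxQy = 8740,
                  f_QxQy = 0.1, f_ByQy = 2.52, f_BxQy = 2.43),
    modes = list(frequency = c(169, 345, 438, 572, 732, 843, 993, 1197,
                               1310, 1511),
                 S_Qy = c(29.5, 22.2, 4.4, 10.3, 27.2, 18.2, 47.4, 29.9,
                          52.1, 36.7) / 1e3,
                 qx_rescale_indices = c(1, 2, 3),
                 qx_displacement_factor = 3),
    vc_mode = list(frequency = 1500, coupling_scaled = 750, max_quanta = 4),
    bath = list(s1 = 0.402, s2 = 0.398, omega1 = 0.557, omega2 = 1.94,
                temperature = 300, tau_max_fs = 1e4),
    disorder = list(fwhm = fwhm, n_samples = 1000, seed = 1,
                    correlated_qx = FALSE),
    coupling = list(J_QyQy = 83, mask = "all"),
    geometry = list(type = "open_sandwich", distance = 10,
                    tilt = unname(.open_sandwich_defaults["tilt"]),
                    twist = unname(.open_sandwich_defaults["twist"]),
                    azimuth = unname(.open_sandwich_defaults["azimuth"]),
                    skew = unname(.open_sandwich_defaults["skew"]),
                    path = NULL,
                    rotations = as.list(default_dipole_rotations())),
    grid = list(n_t = 4096, dt_fs = 1)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", here, call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
        is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration file,
#' fills unspecified values from the preset defaults (the file may select
#' the preset with a top-level `preset` key) and validates the result.
#' Unknown keys are rejected with their full path.
#'
#' @param path Config file path.  An empty file yields the full default
#'   (WSCP) configuration.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  preset <- if (!is.null(user$preset)) user$preset else "wscp"
  cfg <- merge_config(default_config(preset), user)
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Resolves every section through its constructor so that all invariants
#' (positive frequencies, non-negative FWHM values, known masks, ...) are
#' checked, with the offending section named in the error.
#'
#' @param cfg A `run_config` list.
#' @return The configuration, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  # constructors carry the detailed invariants; surface their errors with
  # field-level context
  ctx <- function(section, expr) {
    tryCatch(expr, error = function(e) {
      stop("config section [", section, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  ctx("modes/states/vc_mode", config_monomer_params(cfg))
  ctx("bath", config_bath(cfg))
  ctx("disorder", config_disorder(cfg))
  if (!cfg$coupling$mask %in% c("all", "zero_zero_only")) {
    stop("config section [coupling]: unknown mask ", cfg$coupling$mask,
         call. = FALSE)
  }
  invisible(cfg)
}

#' Write the fully resolved configuration (provenance record)
#'
#' @param config A `run_config`.
#' @param path Output path; format by extension (YAML default, JSON for
#'   `.json`).
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Resolve configuration sections into model objects
#'
#' `config_monomer_params()`, `config_bath()`, `config_disorder()`,
#' `config_geometry()` and `config_grid()` turn the corresponding sections
#' of a [default_config()]-style list into the package's parameter objects.
#'
#' @param config A `run_config`.
#' @param states_include Optional override of the included electronic
#'   states (used by the model-ablation variants).
#' @return The corresponding parameter object.
#' @export
config_monomer_params <- function(config, states_include = NULL) {
  s <- config$states
  include <- if (is.null(states_include)) s$include else states_include
  st <- electronic_states(include, dE_QxQy = s$dE_QxQy, dE_ByQy = s$dE_ByQy,
                          dE_BxQy = s$dE_BxQy, f_QxQy = s$f_QxQy,
                          f_ByQy = s$f_ByQy, f_BxQy = s$f_BxQy)
  m <- config$modes
  cat <- mode_catalog(m$frequency, m$S_Qy)
  if (length(m$qx_rescale_indices)) {
    cat <- rescale_qx_modes(cat, m$qx_rescale_indices,
                            m$qx_displacement_factor)
  }
  v <- config$vc_mode
  monomer_params(states = st, modes = cat,
                 vc = vc_mode(v$frequency, v$coupling_scaled, v$max_quanta),
                 qy_energy_absolute = config$qy_energy_absolute,
                 inhomogeneous_fwhm = unlist(config$disorder$fwhm))
}

#' @rdname config_monomer_params
#' @export
config_bath <- function(config) {
  b <- config$bath
  bath_params(b$s1, b$s2, b$omega1, b$omega2, b$temperature, b$tau_max_fs)
}

#' @rdname config_monomer_params
#' @export
config_disorder <- function(config) {
  d <- config$disorder
  disorder_model(unlist(d$fwhm), d$n_samples, d$seed, d$correlated_qx)
}

#' @rdname config_monomer_params
#' @export
config_geometry <- function(config) {
  g <- config$geometry
  rot <- unlist(g$rotations)
  if (identical(g$type, "open_sandwich")) {
    return(open_sandwich_dimer(g$distance, g$tilt, g$twist, g$azimuth,
                               g$skew, rotations = rot))
  }
  if (identical(g$type, "file")) {
    geoms <- if (grepl("\\.pdb$", g$path, ignore.case = TRUE)) {
      read_pigment_geometry_pdb(g$path, rotations = rot)
    } else {
      read_pigment_geometry(g$path, rotations = rot)
    }
    if (length(geoms) < 2) stop("geometry file holds fewer than two pigments",
                                call. = FALSE)
    return(structure(geoms[1:2], class = "dimer_geometry"))
  }
  stop("unknown geometry type: ", g$type, call. = FALSE)
}

#' @rdname config_monomer_params
#' @export
config_grid <- function(config) {
  spectrum_grid(config$grid$n_t, config$grid$dt_fs)
}
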