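#' Pigment geometry
#'
#' A pigment is represented by its center (taken as the reference point of
#' the magnetic-dipole construction), two in-plane base axes (the connecting
#' vectors of opposite pyrrole nitrogens: `base_y` for N_D -> N_B carrying
#' Qy, `base_x` for N_C -> N_A carrying Qx), the ring-plane normal, and the
#' in-plane rotation angles applied to the transition-dipole directions.
#' Positive rotation angles rotate from the Qy axis toward the Qx axis.
#'
#' @param center 3-vector, Angstrom.
#' @param base_x,base_y In-plane base direction vectors (normalized
#'   internally; need not be exactly orthogonal, as nitrogen connecting
#'   vectors in real pigments are not).
#' @param rotations Named angles (degrees) for `Qy`, `Qx`, `By`, `Bx`.
#'   Defaults -7, 20, 20, -20 degrees.
#' @return Object of class `pigment_geometry`.
#' @export
pigment_geometry <- function(center = c(0, 0, 0),
                             base_x = c(1, 0, 0), base_y = c(0, 1, 0),
                             rotations = default_dipole_rotations()) {
  base_x <- normalize3(base_x)
  base_y <- normalize3(base_y)
  nrm <- cross3(rbind(base_x), rbind(base_y))[1, ]
  if (sqrt(sum(nrm^2)) < 1e-8) {
    stop("base axes are (nearly) collinear; plane normal undefined", call. = FALSE)
  }
  full <- default_dipole_rotations()
  rotations <- unlist(rotations)
  full[names(rotations)] <- rotations
  structure(list(center = as.numeric(center), base_x = base_x, base_y = base_y,
                 normal = normalize3(nrm), rotations = full),
            class = "pigment_geometry")
}

#' @rdname pigment_geometry
#' @export
default_dipole_rotations <- function() c(Qy = -7, Qx = 20, By = 20, Bx = -20)

#' @rdname pigment_geometry
#' @export
default_pigment_geometry <- function() pigment_geometry()

normalize3 <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# rotate v in the pigment plane by `deg` degrees about the plane normal z;
# positive angles rotate the Qx base axis toward the Qy base axis (the sense
# is a convention; this choice reproduces the printed WSCP coupling table)
rotate_in_plane <- function(v, deg, z) {
  th <- deg * pi / 180
  zv <- cross3(rbind(z), rbind(v))[1, ]
  cos(th) * v + sin(th) * zv
}

#' Transition-dipole unit vectors of a pigment
#'
#' Applies the configured in-plane rotations: Qy from `base_y`, Qx from
#' `base_x`, By from `base_y`, Bx from `base_x`.
#'
#' @param geometry A [pigment_geometry()].
#' @return 4 x 3 matrix with rows `Qy`, `Qx`, `By`, `Bx`, unit norm.
#' @export
dipole_directions <- function(geometry) {
  stopifnot(inherits(geometry, "pigment_geometry"))
  z <- geometry$normal
  out <- rbind(
    Qy = rotate_in_plane(geometry$base_y, geometry$rotations[["Qy"]], z),
    Qx = rotate_in_plane(geometry$base_x, geometry$rotations[["Qx"]], z),
    By = rotate_in_plane(geometry$base_y, geometry$rotations[["By"]], z),
    Bx = rotate_in_plane(geometry$base_x, geometry$rotations[["Bx"]], z))
  out / sqrt(rowSums(out^2))
}

#' Pigment geometry from pyrrole nitrogen coordinates
#'
#' The Qy base direction is the connecting vector from N_D to N_B, the Qx
#' base direction the one from N_C to N_A; both are then rotated in the ring
#' plane by the configured angles.
#'
#' @param n_a,n_b,n_c,n_d 3-vectors (Angstrom) of the four pyrrole nitrogens.
#' @param center Optional pigment center; defaults to the nitrogen centroid.
#' @param rotations Dipole rotation angles, see [pigment_geometry()].
#' @return A [pigment_geometry()].
#' @export
dipoles_from_nitrogens <- function(n_a, n_b, n_c, n_d, center = NULL,
                                   rotations = default_dipole_rotations()) {
  if (is.null(center)) center <- (n_a + n_b + n_c + n_d) / 4
  pigment_geometry(center = center, base_x = n_a - n_c, base_y = n_b - n_d,
                   rotations = rotations)
}

#' Specification of a synthetic C2-symmetric "open sandwich" dimer
#'
#' Generates a two-pigment geometry related by a twofold rotation about the
#' global z axis, with centers at `(-d/2, 0, 0)` and `(+d/2, 0, 0)`.  The
#' first pigment's frame is the standard frame rotated by
#' `Rz(azimuth) Ry(tilt) Rz(twist)`; `skew` tilts the Qx base axis toward
#' the Qy base axis in-plane (nitrogen connecting vectors of real pigments
#' are not exactly orthogonal).  The defaults are calibrated so that, with
#' the standard dipole rotations and the transition-dipole ratios of
#' chlorophyll a, [scaled_couplings()] anchored to J(QyQy) = 83 cm^-1
#' reproduces the full WSCP coupling table (see the methods vignette).
#'
#' @param distance Inter-center distance in Angstrom (> 3).
#' @param tilt,twist,azimuth Orientation angles of pigment 1 in degrees.
#' @param skew In-plane skew of the Qx base axis in degrees.
#' @param rotations Dipole rotation angles, see [pigment_geometry()].
#' @return List of two [pigment_geometry()] objects, class `dimer_geometry`.
#' @export
open_sandwich_dimer <- function(distance = 10,
                                tilt = .open_sandwich_defaults["tilt"],
                                twist = .open_sandwich_defaults["twist"],
                                azimuth = .open_sandwich_defaults["azimuth"],
                                skew = .open_sandwich_defaults["skew"],
                                rotations = default_dipole_rotations()) {
  if (distance <= 3) stop("`distance` must exceed 3 Angstrom", call. = FALSE)
  d2r <- pi / 180
  base_x <- c(cos(skew * d2r), sin(skew * d2r), 0)
  base_y <- c(0, 1, 0)
  R <- rot_z(azimuth * d2r) %*% rot_y(tilt * d2r) %*% rot_z(twist * d2r)
  ax <- as.numeric(R %*% base_x)
  ay <- as.numeric(R %*% base_y)
  c2 <- diag(c(-1, -1, 1))
  g1 <- pigment_geometry(center = c(-distance / 2, 0, 0),
                         base_x = ax, base_y = ay, rotations = rotations)
  g2 <- pigment_geometry(center = c(+distance / 2, 0, 0),
                         base_x = as.numeric(c2 %*% ax),
                         base_y = as.numeric(c2 %*% ay), rotations = rotations)
  structure(list(g1, g2), class = "dimer_geometry")
}

rot_z <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
rot_y <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))

#' Read pigment geometries from a coordinate table
#'
#' The primary plain-text geometry format: a TSV with columns `pigment`,
#' `atom`, `x`, `y`, `z` (Angstrom).  Recognized atoms are the pyrrole
#' nitrogens `NA`, `NB`, `NC`, `ND` and an optional `CENTER` row (defaults
#' to the nitrogen centroid).
#'
#' In addition to atom positions, the table may carry `BASEX` and `BASEY`
#' rows holding the in-plane base *vectors* (center-relative, as written by
#' [write_pigment_geometry()]); when present they take precedence over the
#' nitrogen differences, making the write/read round trip bit-exact.
#'
#' @param path File path.
#' @param rotations Dipole rotation angles, see [pigment_geometry()].
#' @return List of [pigment_geometry()] objects, one per pigment, in order
#'   of first appearance.
#' @export
read_pigment_geometry <- function(path, rotations = default_dipole_rotations()) {
  # na.strings must stay empty: "NA" is a pyrrole nitrogen name here
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = character(),
                           colClasses = c("character", "character",
                                          "numeric", "numeric", "numeric"))
  names(tab) <- tolower(names(tab))
  need <- c("pigment", "atom", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("geometry table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (p in unique(tab$pigment)) {
    sub <- tab[tab$pigment == p, , drop = FALSE]
    get <- function(atom) {
      r <- sub[toupper(sub$atom) == atom, , drop = FALSE]
      if (nrow(r) != 1) stop("pigment ", p, ": need exactly one ", atom,
                             " atom", call. = FALSE)
      c(r$x, r$y, r$z)
    }
    ctr <- if (any(toupper(sub$atom) == "CENTER")) get("CENTER") else NULL
    if (all(c("BASEX", "BASEY") %in% toupper(sub$atom))) {
      if (is.null(ctr)) stop("pigment ", p, ": BASEX/BASEY rows need a ",
                             "CENTER row", call. = FALSE)
      out[[p]] <- pigment_geometry(center = ctr, base_x = get("BASEX"),
                                   base_y = get("BASEY"),
                                   rotations = rotations)
    } else {
      out[[p]] <- dipoles_from_nitrogens(get("NA"), get("NB"), get("NC"),
                                         get("ND"), center = ctr,
                                         rotations = rotations)
    }
  }
  out
}

#' Write pigment geometries to the coordinate-table format
#'
#' Emits synthetic nitrogen positions at unit distance from the center along
#' the stored base axes, plus the explicit center and the exact base
#' vectors (`BASEX`/`BASEY` rows), so that [read_pigment_geometry()]
#' reconstructs the geometry bit-exactly.
#'
#' @param geometries List of [pigment_geometry()] objects.
#' @param path Output file path.
#' @export
write_pigment_geometry <- function(geometries, path) {
  rows <- list()
  for (i in seq_along(geometries)) {
    g <- geometries[[i]]
    stopifnot(inherits(g, "pigment_geometry"))
    nm <- if (!is.null(names(geometries)) && nzchar(names(geometries)[i]))
      names(geometries)[i] else paste0("pigment", i)
    at <- rbind(g$center + g$base_x, g$center + g$base_y,
                g$center - g$base_x, g$center - g$base_y, g$center,
                g$base_x, g$base_y)
    # 17 significant digits: doubles survive the text round-trip exactly
    rows[[i]] <- data.frame(pigment = nm,
                            atom = c("NA", "NB", "NC", "ND", "CENTER",
                                     "BASEX", "BASEY"),
                            x = sprintf("%.17g", at[, 1]),
                            y = sprintf("%.17g", at[, 2]),
                            z = sprintf("%.17g", at[, 3]))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read chlorophyll pigment geometries from a PDB file
#'
#' Extracts, per chlorophyll residue (residue names `CLA`, `CHL`, `CL0`,
#' `CLB`), the four pyrrole nitrogens `NA`/`NB`/`NC`/`ND` and uses their
#' centroid as the pigment center.  Requires the `bio3d` package.
#'
#' @param path PDB file path.
#' @param resid Residue names treated as chlorophyll.
#' @param rotations Dipole rotation angles, see [pigment_geometry()].
#' @return List of [pigment_geometry()] objects keyed by `chain_resno`.
#' @export
read_pigment_geometry_pdb <- function(path, resid = c("CLA", "CHL", "CL0", "CLB"),
                                      rotations = default_dipole_rotations()) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB geometries requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$resid %in% resid & toupper(at$elety) %in% c("NA", "NB", "NC", "ND"), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("no chlorophyll pyrrole nitrogens found", call. = FALSE)
  key <- paste(at$chain, at$resno, sep = "_")
  out <- list()
  for (k in unique(key)) {
    sub <- at[key == k, , drop = FALSE]
    get <- function(name) {
      r <- sub[toupper(sub$elety) == name, , drop = FALSE]
      if (nrow(r) != 1) stop("residue ", k, ": need exactly one ", name,
                             " atom", call. = FALSE)
      c(r$x, r$y, r$z)
    }
    out[[k]] <- dipoles_from_nitrogens(get("NA"), get("NB"), get("NC"),
                                       get("ND"), rotations = rotations)
  }
  out
}
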