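#' Physical constants used throughout the package
#'
#' Unit conventions are global: lengths in nm, times in ns, energies in
#' kcal/mol (unless a field is explicitly in kT), currents in pA, potentials
#' in mV, conductances in pS.
#'
#' @return Named list with `kB` (kcal/mol/K), `T_default` (K), `e_charge`
#'   (C), `eps0` (F/m), `ev_kcal` (kcal/mol per eV), and `kJ_per_kcal`.
#' @export
channel_constants <- function() {
  list(
    kB          = 0.0019872,        # kcal/mol/K
    T_default   = 300,              # K
    e_charge    = 1.602176634e-19,  # C
    eps0        = 8.8541878128e-12, # F/m
    ev_kcal     = 23.060548,        # kcal/mol per eV (e * NA / 4184)
    kJ_per_kcal = 4.184
  )
}

#' Thermal energy in kcal/mol
#'
#' @param T temperature in K (default 300)
#' @return kB*T in kcal/mol
#' @export
#' @examples
#' kt_kcal(300)  # 0.59616
kt_kcal <- function(T = 300) {
  0.0019872 * T
}

## internal shorthands
.E_CHARGE <- 1.602176634e-19
.EV_KCAL <- 23.060548
.EPS0 <- 8.8541878128e-12

#' Construct an ion trajectory
#'
#' The universal input container: per-frame 3D positions of tracked
#' particles (ions, ligand beads, lipid headgroup markers) with species
#' labels, charge valences, per-frame orthorhombic box dimensions and a
#' fixed frame interval. Frames are 0-based in time: frame i is at
#' `t0 + i*dt`.
#'
#' @param coords numeric array `[n_frames, n_particles, 3]`, positions in nm
#' @param ids integer particle identifiers (unique)
#' @param species character label per particle
#' @param valence signed integer charge per particle (e.g. +1 Na+, +2 Ca2+,
#'   -1 Cl-); must be consistent within a species
#' @param box per-frame box dimensions, either a length-3 vector (constant
#'   box) or an `[n_frames, 3]` matrix, nm. Orthorhombic only.
#' @param dt time per frame, ns
#' @param t0 time of the first frame, ns
#' @param metadata free-form list (generators record ground truth here)
#' @return object of class `ion_trajectory`
#' @export
ion_trajectory <- function(coords, ids, species, valence, box, dt, t0 = 0,
                           metadata = list()) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an [n_frames, n_particles, 3] array")
  nf <- dim(coords)[1]
  np <- dim(coords)[2]
  if (nf < 2L) stop("trajectory must have at least 2 frames")
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  if (length(ids) != np || anyDuplicated(ids))
    stop("ids must be unique, one per particle")
  if (length(species) != np) stop("species must have one label per particle")
  if (length(valence) != np) stop("valence must have one value per particle")
  ## one valence per species
  vmap <- tapply(valence, species, function(v) length(unique(v)))
  if (any(vmap > 1L)) {
    bad <- names(vmap)[vmap > 1L]
    stop("inconsistent valence within species: ", paste(bad, collapse = ", "))
  }
  if (is.matrix(box)) {
    if (nrow(box) != nf || ncol(box) != 3L)
      stop("box matrix must be [n_frames, 3]")
  } else {
    if (length(box) != 3L) stop("box must be length 3 or [n_frames, 3]")
    box <- matrix(rep(box, each = nf), nrow = nf)
  }
  if (!all(is.finite(box)) || any(box <= 0)) stop("box dimensions must be > 0")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  structure(list(
    coords = coords, ids = as.integer(ids), species = as.character(species),
    valence = as.integer(valence), box = box, dt = dt, t0 = t0,
    metadata = metadata
  ), class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("ion_trajectory: %d particles x %d frames (dt = %g ns)\n",
              n_particles(x), n_frames(x), x$dt))
  tab <- table(x$species)
  cat("  species:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @rdname ion_trajectory
#' @param traj an `ion_trajectory`
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname ion_trajectory
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

#' @rdname ion_trajectory
#' @export
frame_times <- function(traj) traj$t0 + (seq_len(n_frames(traj)) - 1L) * traj$dt

#' Channel pathway geometry
#'
#' Defines the permeation pathway as a cylinder along the membrane normal:
#' a compartment-boundary plane at `boundary_z` with a radial cutoff, and
#' end planes `extent_out` above (extracellular) and `extent_in` below
#' (intracellular) the boundary. The axial coordinate increases from the
#' intracellular to the extracellular side; outer-to-inner traversals move
#' in the negative axial direction but are reported with POSITIVE sign
#' (the field's plotting convention) -- this sign map lives here and only
#' here.
#'
#' Defaults follow the computational-electrophysiology convention for a
#' pentameric channel: 1.2 nm cylinder radius, 7.5 nm toward the
#' extracellular domain and 5 nm toward the intracellular domain.
#'
#' @param boundary_z axial coordinate of the compartment boundary, nm
#' @param axis unit 3-vector; only the membrane normal (+/- z) is supported
#' @param cyl_radius radial cutoff, nm
#' @param extent_out distance from the boundary toward the extracellular
#'   side, nm
#' @param extent_in distance toward the intracellular side, nm
#' @param center_xy axis position in the membrane plane, nm
#' @param n_membranes 1 (single bilayer) or 2 (double-bilayer setup)
#' @param second_boundary_z boundary of the second (antiparallel) channel
#'   copy; required iff `n_membranes == 2`
#' @return object of class `channel_geometry`
#' @export
channel_geometry <- function(boundary_z, axis = c(0, 0, 1), cyl_radius = 1.2,
                             extent_out = 7.5, extent_in = 5.0,
                             center_xy = c(0, 0), n_membranes = 1,
                             second_boundary_z = NULL) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8) stop("axis must be a unit vector")
  if (sum(abs(axis[1:2])) > 1e-8)
    stop("only the z membrane normal is supported as the channel axis")
  if (cyl_radius <= 0) stop("cyl_radius must be > 0")
  if (extent_out <= 0 || extent_in <= 0) stop("extents must be > 0")
  if (n_membranes == 2 && is.null(second_boundary_z))
    stop("second_boundary_z is required for a double-bilayer geometry")
  if (n_membranes == 1 && !is.null(second_boundary_z))
    stop("second_boundary_z only applies when n_membranes == 2")
  structure(list(
    boundary_z = boundary_z, axis = axis / sqrt(sum(axis^2)),
    cyl_radius = cyl_radius, extent_out = extent_out, extent_in = extent_in,
    center_xy = center_xy, n_membranes = as.integer(n_membranes),
    second_boundary_z = second_boundary_z,
    ## sign map: traversal along -z (outer -> inner) is reported as +1
    positive_direction = "outer_to_inner"
  ), class = "channel_geometry")
}

#' Write a trajectory in the tabular dialect
#'
#' Self-contained CSV dialect used by all tests: comment header carrying
#' `dt` and `t0`, then one row per (frame, particle) with columns
#' frame,id,species,valence,x,y,z,box_x,box_y,box_z. Frames are 0-based.
#'
#' @param traj an `ion_trajectory`
#' @param path output file
#' @export
save_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ion_trajectory"))
  nf <- n_frames(traj); np <- n_particles(traj)
  fr <- rep(seq_len(nf) - 1L, each = np)
  df <- data.frame(
    frame = fr,
    id = rep(traj$ids, nf),
    species = rep(traj$species, nf),
    valence = rep(traj$valence, nf),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])),
    box_x = rep(traj$box[, 1], each = np),
    box_y = rep(traj$box[, 2], each = np),
    box_z = rep(traj$box[, 3], each = np)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# poreflux-trajectory v1",
               sprintf("# dt_ns=%.17g t0_ns=%.17g", traj$dt, traj$t0)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a trajectory from the tabular dialect
#'
#' @param path input file written by [save_trajectory()] (or by hand in the
#'   same dialect)
#' @param format only `"csv"` is built in
#' @param selection optional character vector of species to keep
#' @return an `ion_trajectory`
#' @export
load_trajectory <- function(path, format = "csv", selection = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, "csv")
  hdr <- readLines(path, n = 2L)
  m <- regmatches(hdr[2], regexec("dt_ns=([^ ]+) t0_ns=([^ ]+)", hdr[2]))[[1]]
  if (length(m) != 3L)
    stop("format error: missing dt/t0 header in ", path)
  dt <- as.numeric(m[2]); t0 <- as.numeric(m[3])
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "id", "species", "valence", "x", "y", "z",
            "box_x", "box_y", "box_z")
  if (!all(need %in% names(df)))
    stop("format error: expected columns ", paste(need, collapse = ","))
  if (nrow(df) == 0L) stop("empty input: no frames in ", path)
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad))
    stop(sprintf("format error: non-finite coordinate at frame %d (row %d)",
                 df$frame[bad[1]], bad[1]))
  if (!is.null(selection)) {
    df <- df[df$species %in% selection, , drop = FALSE]
    if (nrow(df) == 0L)
      stop("empty input: selection matches no particles")
  }
  frames <- sort(unique(df$frame))
  ids <- unique(df$id)
  np <- length(ids); nf <- length(frames)
  if (nf < 2L) stop("empty input: need at least 2 frames")
  ## order rows as frame-major, id within frame, preserving input id order
  df$.fi <- match(df$frame, frames)
  df$.pi <- match(df$id, ids)
  o <- order(df$.fi, df$.pi)
  df <- df[o, ]
  if (nrow(df) != nf * np)
    stop("format error: particle set is not constant across frames")
  coords <- array(NA_real_, c(nf, np, 3))
  coords[, , 1] <- matrix(df$x, nrow = nf, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nrow = nf, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nrow = nf, byrow = TRUE)
  box <- cbind(df$box_x[df$.pi == 1L], df$box_y[df$.pi == 1L],
               df$box_z[df$.pi == 1L])
  first <- df[df$.fi == 1L, ]
  ion_trajectory(coords, ids = first$id, species = first$species,
                 valence = first$valence, box = box, dt = dt, t0 = t0)
}

#' Save a result table
#'
#' @param records non-empty data.frame of homogeneous result rows
#' @param path output file
#' @param format `"csv"` or `"json"`
#' @export
save_table <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty input: no records to save")
  if (format == "csv") {
    utils::write.csv(format(records, digits = 17, scientific = NA,
                            trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(records, path, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") utils::read.csv(path)
  else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Free-energy profile container
#'
#' Free energy as a function of an axial coordinate, bulk-referenced so the
#' minimum over the bulk region is 0. Unsampled bins are NA (never +/-Inf).
#'
#' @param coord grid, nm
#' @param energy free energy, kcal/mol
#' @param uncertainty optional per-bin uncertainty, kcal/mol
#' @param bulk_region optional c(lo, hi) interval used for referencing
#' @export
pmf_profile <- function(coord, energy, uncertainty = NULL,
                        bulk_region = NULL) {
  stopifnot(length(coord) == length(energy))
  if (any(is.infinite(energy))) energy[is.infinite(energy)] <- NA_real_
  structure(list(coord = coord, energy = energy, uncertainty = uncertainty,
                 bulk_region = bulk_region), class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins on [%.3g, %.3g] nm, range [%.3g, %.3g] kcal/mol\n",
              length(x$coord), min(x$coord), max(x$coord),
              min(x$energy, na.rm = TRUE), max(x$energy, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  d <- data.frame(coord_nm = x$coord, energy_kcal = x$energy)
  if (!is.null(x$uncertainty)) d$uncertainty_kcal <- x$uncertainty
  d
}
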