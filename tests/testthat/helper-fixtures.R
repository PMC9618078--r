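# build a trajectory from prescribed axial tracks (frames x particles),
# lateral coordinates fixed at the pathway axis unless given
make_z_traj <- function(z, box = c(6, 6, 10), x = 3, y = 3, dt = 0.1,
                        species = NULL, valence = NULL) {
  z <- as.matrix(z)
  nf <- nrow(z); np <- ncol(z)
  if (is.null(species)) species <- rep("Na", np)
  if (is.null(valence)) valence <- rep(1L, np)
  coords <- array(NA_real_, c(nf, np, 3))
  coords[, , 1] <- x
  coords[, , 2] <- y
  coords[, , 3] <- z
  ion_trajectory(coords, ids = seq_len(np), species = species,
                 valence = valence, box = box, dt = dt)
}

# standard test geometry matching the synthetic box (10 nm axial extent,
# pathway centered at (3, 3))
std_geom <- function(...) {
  channel_geometry(boundary_z = 5, cyl_radius = 1.2, extent_out = 2.5,
                   extent_in = 2.5, center_xy = c(3, 3), ...)
}

std_spec <- function(voltage = 0, seed = 1, n_ions = 50L, pmf = NULL, ...) {
  args <- list(diffusion = c(Na = 1), valence = c(Na = 1L),
               n_ions = c(Na = n_ions), voltage = voltage,
               channel_span = c(3, 7), box = c(6, 6, 10), dt = 0.01,
               cyl_radius = 1.0, seed = seed)
  if (!is.null(pmf)) args$pmf <- pmf
  args <- utils::modifyList(args, list(...))
  do.call(channel_sim_spec, args)
}
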