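#' Specification of a synthetic drift-diffusion channel system
#'
#' Describes the 1D overdamped-Langevin system the generator integrates:
#' ions diffuse along the membrane normal in a periodic (or reflective) box,
#' feeling a potential of mean force `pmf(z)` plus an applied transmembrane
#' potential dropped linearly across `channel_span`. Laterally, ions diffuse
#' inside the pathway cylinder. This emulates the statistical structure of
#' applied-field simulations of an open channel with known ground truth.
#'
#' @param pmf vectorized function U(z) in kcal/mol, defined on [0, box_z]
#' @param diffusion named vector, diffusion coefficient per species, nm^2/ns
#' @param valence named vector, signed integer charge per species
#' @param n_ions named vector, ions per species
#' @param voltage applied potential V, mV; the extracellular (high-z) side
#'   sits at `voltage`, the intracellular side at 0, with a linear drop
#'   across `channel_span`
#' @param channel_span c(z_lo, z_hi), nm, inside the box
#' @param box c(x, y, z) box dimensions, nm
#' @param dt integration time step, ns (default 0.01)
#' @param cyl_radius lateral confinement radius, nm
#' @param periodic logical; TRUE wraps z periodically (sustains steady-state
#'   flux), FALSE reflects at the box ends
#' @param seed integer RNG seed
#' @return object of class `channel_sim_spec`
#' @export
channel_sim_spec <- function(pmf = function(z) rep(0, length(z)),
                             diffusion = c(NA_ion = 1),
                             valence = c(NA_ion = 1L),
                             n_ions = c(NA_ion = 20L),
                             voltage = 0,
                             channel_span = c(3, 7),
                             box = c(6, 6, 10),
                             dt = 0.01,
                             cyl_radius = 1.2,
                             periodic = TRUE,
                             seed = 1L) {
  sp <- names(n_ions)
  if (is.null(sp) || !all(sp %in% names(diffusion)) ||
      !all(sp %in% names(valence)))
    stop("diffusion, valence and n_ions must be named by species")
  if (any(diffusion <= 0)) stop("diffusion coefficients must be > 0")
  if (any(box <= 0) || length(box) != 3L) stop("box must be positive length 3")
  if (channel_span[1] >= channel_span[2] ||
      channel_span[1] < 0 || channel_span[2] > box[3])
    stop("channel_span must be an increasing interval inside the box")
  ztest <- seq(0, box[3], length.out = 512)
  if (!all(is.finite(pmf(ztest)))) stop("pmf must be finite on [0, box_z]")
  structure(list(pmf = pmf, diffusion = diffusion, valence = valence,
                 n_ions = n_ions, voltage = voltage,
                 channel_span = channel_span, box = box, dt = dt,
                 cyl_radius = cyl_radius, periodic = periodic,
                 seed = as.integer(seed)),
            class = "channel_sim_spec")
}

## applied potential phi(z) in mV: 0 on the intracellular (low-z) side,
## `voltage` on the extracellular side, linear across the span
.phi_mV <- function(z, spec) {
  lo <- spec$channel_span[1]; hi <- spec$channel_span[2]
  spec$voltage * pmin(pmax((z - lo) / (hi - lo), 0), 1)
}

## total potential in kcal/mol for charge q
.u_total <- function(z, spec, q) {
  spec$pmf(z) + q * .phi_mV(z, spec) / 1000 * .EV_KCAL
}

#' Simulate ion tracks through a channel by overdamped Langevin dynamics
#'
#' Per-step update along z: `dz = -(D/kT) dU/dz dt + sqrt(2 D dt) xi`, with
#' `U = pmf(z) + q e phi(z)`. Lateral coordinates diffuse with the same D,
#' reflected at the pathway cylinder radius. A stability guard rejects time
#' steps for which the deterministic energy change per step would exceed
#' 2 kT anywhere on the grid.
#'
#' @param spec a [channel_sim_spec()]
#' @param n_steps number of integration steps (>= 1)
#' @param save_every store every k-th step as a frame (default 1)
#' @param T temperature, K
#' @return an [ion_trajectory()]; `metadata$ground_truth` records the spec,
#'   the drift field and the applied potential
#' @export
simulate_ion_channel <- function(spec, n_steps, save_every = 1L, T = 300) {
  stopifnot(inherits(spec, "channel_sim_spec"), n_steps >= 1)
  kT <- kt_kcal(T)
  Lz <- spec$box[3]
  species <- rep(names(spec$n_ions), spec$n_ions)
  q <- spec$valence[species]
  D <- spec$diffusion[species]
  n <- length(species)

  ## gradient of total potential by central difference, per species charge
  h <- 1e-5
  grad_u <- function(z, qv) {
    (.u_total(z + h, spec, qv) - .u_total(z - h, spec, qv)) / (2 * h)
  }
  ## stability guard: |deterministic dU per step| <= 2 kT on a fine grid
  zg <- seq(0, Lz, length.out = 2048)
  for (s in unique(species)) {
    g <- abs(grad_u(zg, spec$valence[s]))
    dU_step <- (spec$diffusion[s] / kT) * g^2 * spec$dt
    if (max(dU_step) > 2 * kT)
      stop(sprintf(paste0("stability error: dt = %g ns too large for the ",
                          "PMF gradient of species %s (max |dU| per step ",
                          "%.3g kcal/mol > 2 kT); reduce dt"),
                   spec$dt, s, max(dU_step)))
  }

  set.seed(spec$seed)
  z <- stats::runif(n, 0, Lz)
  r0 <- spec$cyl_radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cx <- spec$box[1] / 2; cy <- spec$box[2] / 2
  x <- cx + r0 * cos(th); y <- cy + r0 * sin(th)

  nf <- n_steps %/% save_every
  coords <- array(NA_real_, c(nf, n, 3))
  sq <- sqrt(2 * D * spec$dt)
  fac <- D / kT * spec$dt
  fi <- 0L
  for (step in seq_len(n_steps)) {
    z <- z - fac * grad_u(z, q) + sq * stats::rnorm(n)
    if (spec$periodic) {
      z <- z %% Lz
    } else {
      z <- abs(z)
      over <- z > Lz
      z[over] <- 2 * Lz - z[over]
      z <- pmin(pmax(z, 0), Lz)  # guard rare double reflection
    }
    x <- x + sq * stats::rnorm(n)
    y <- y + sq * stats::rnorm(n)
    ## radial reflection at the pathway cylinder
    dx <- x - cx; dy <- y - cy
    r <- sqrt(dx^2 + dy^2)
    out <- r > spec$cyl_radius
    if (any(out)) {
      rr <- pmin(pmax(2 * spec$cyl_radius - r[out], 0), spec$cyl_radius)
      x[out] <- cx + dx[out] / r[out] * rr
      y[out] <- cy + dy[out] / r[out] * rr
    }
    if (step %% save_every == 0L) {
      fi <- fi + 1L
      coords[fi, , 1] <- x; coords[fi, , 2] <- y; coords[fi, , 3] <- z
    }
  }
  ion_trajectory(
    coords, ids = seq_len(n), species = species, valence = q,
    box = spec$box, dt = spec$dt * save_every,
    metadata = list(ground_truth = list(
      spec = spec, T = T,
      phi_mV = function(z) .phi_mV(z, spec),
      drift = function(z, s) -spec$diffusion[s] / kT *
        grad_u(z, spec$valence[s])
    ))
  )
}

#' Apply computational-electrophysiology style position swaps
#'
#' Emulates the double-bilayer ion/water swapping scheme at the analysis
#' level: every `swap_every` frames the charge imbalance between the two
#' membrane-delimited compartments is compared with `target_imbalance`, and
#' if it deviates by at least `threshold` one ion and one zero-valence
#' placeholder particle exchange compartments by position teleport (their
#' position histories are exchanged from that frame on). All teleports are
#' recorded in `metadata$swaps` so that detectors can be tested against
#' them. Swaps are applied instantaneously (no multi-step smoothing).
#'
#' @param traj an [ion_trajectory()] containing ions and zero-valence
#'   placeholder particles
#' @param geometry a double-bilayer [channel_geometry()] (`n_membranes = 2`)
#' @param target_imbalance target charge difference A - B, units of e;
#'   compartment A lies between the two boundary planes
#' @param swap_every check interval, frames
#' @param threshold minimum deviation triggering a swap (default 1)
#' @return modified trajectory with `metadata$swaps` (data.frame: frame,
#'   ion_id, placeholder_id)
#' @export
apply_compel_swaps <- function(traj, geometry, target_imbalance,
                               swap_every = 100L, threshold = 1) {
  stopifnot(inherits(traj, "ion_trajectory"),
            inherits(geometry, "channel_geometry"))
  if (geometry$n_membranes != 2L)
    stop("CompEL swaps require a double-bilayer geometry (n_membranes = 2)")
  b1 <- min(geometry$boundary_z, geometry$second_boundary_z)
  b2 <- max(geometry$boundary_z, geometry$second_boundary_z)
  coords <- traj$coords
  val <- traj$valence
  nf <- n_frames(traj)
  in_A <- function(z) z > b1 & z < b2
  swaps <- list()
  for (f in seq(swap_every, nf, by = swap_every)) {
    z <- coords[f, , 3]
    imb <- sum(val[in_A(z)]) - sum(val[!in_A(z)])
    dev <- target_imbalance - imb
    if (abs(dev) < threshold) next
    ## move one charge in the direction that reduces the deviation:
    ## dev > 0 -> need more + charge in A (cation B->A or anion A->B)
    a <- in_A(z)
    cand <- if (dev > 0) {
      c(which(val > 0 & !a), which(val < 0 & a))
    } else {
      c(which(val > 0 & a), which(val < 0 & !a))
    }
    plc <- if (length(cand)) {
      ion <- cand[1]
      which(val == 0 & (in_A(z) != a[ion]))
    } else integer(0)
    if (!length(cand) || !length(plc)) {
      warning(sprintf("frame %d: no eligible ion/placeholder to swap; %s",
                      f, "imbalance left uncorrected this cycle"))
      next
    }
    p <- plc[1]
    tmp <- coords[f:nf, ion, , drop = FALSE]
    coords[f:nf, ion, ] <- coords[f:nf, p, ]
    coords[f:nf, p, ] <- tmp
    swaps[[length(swaps) + 1L]] <-
      data.frame(frame = f, ion_id = traj$ids[ion],
                 placeholder_id = traj$ids[p])
  }
  traj$coords <- coords
  traj$metadata$swaps <- if (length(swaps)) do.call(rbind, swaps) else
    data.frame(frame = integer(), ion_id = integer(),
               placeholder_id = integer())
  traj
}

#' Specification of a synthetic deformed-membrane height field
#'
#' Leaflet heights are `+/-(t_bulk/2 - u(r))` plus Gaussian noise, where
#' `u(r) = u0 exp(-|r - center|^2 / (2 sigma^2))` is a localized leaflet
#' compression; thickness is therefore `t_bulk - 2 u(r)`.
#'
#' @param t_bulk unperturbed bilayer thickness, nm
#' @param u0 peak per-leaflet deformation, nm
#' @param sigma Gaussian width of the deformation, nm
#' @param center 2D deformation center, nm
#' @param grid_extent c(Lx, Ly), nm
#' @param grid_spacing cell size, nm
#' @param noise_sd per-cell height noise, nm
#' @param seed integer RNG seed
#' @export
membrane_field_spec <- function(t_bulk = 4.2, u0 = 0.25, sigma = 1.5,
                                center = NULL, grid_extent = c(20, 20),
                                grid_spacing = 0.25, noise_sd = 0.02,
                                seed = 1L) {
  if (t_bulk <= 0) stop("t_bulk must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (grid_spacing <= 0) stop("grid_spacing must be > 0")
  if (is.null(center)) center <- grid_extent / 2
  structure(list(t_bulk = t_bulk, u0 = u0, sigma = sigma, center = center,
                 grid_extent = grid_extent, grid_spacing = grid_spacing,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "membrane_field_spec")
}

#' Generate synthetic leaflet height fields
#'
#' @param spec a [membrane_field_spec()]
#' @return a [membrane_surface_grid()] with the noise-free deformation and
#'   thickness fields stored in `$ground_truth`
#' @export
generate_membrane_surfaces <- function(spec) {
  stopifnot(inherits(spec, "membrane_field_spec"))
  set.seed(spec$seed)
  x <- seq(spec$grid_spacing / 2, spec$grid_extent[1], by = spec$grid_spacing)
  y <- seq(spec$grid_spacing / 2, spec$grid_extent[2], by = spec$grid_spacing)
  d2 <- outer((x - spec$center[1])^2, (y - spec$center[2])^2, "+")
  u <- spec$u0 * exp(-d2 / (2 * spec$sigma^2))
  upper <- (spec$t_bulk / 2 - u) +
    matrix(stats::rnorm(length(u), 0, spec$noise_sd), nrow = length(x))
  lower <- -(spec$t_bulk / 2 - u) +
    matrix(stats::rnorm(length(u), 0, spec$noise_sd), nrow = length(x))
  membrane_surface_grid(
    x = x, y = y, upper = upper, lower = lower,
    mask = matrix(TRUE, length(x), length(y)),
    ground_truth = list(u = u, thickness = spec$t_bulk - 2 * u, spec = spec)
  )
}

#' Sample lipid headgroup marker beads from a synthetic membrane field
#'
#' Companion to [generate_membrane_surfaces()]: scatters headgroup markers
#' uniformly in the membrane plane, placing each on the noise-free leaflet
#' surface plus per-bead Gaussian noise, so that [thickness_map()] can be
#' validated against the generator's ground truth.
#'
#' @param spec a [membrane_field_spec()]
#' @param n_frames frames to generate
#' @param beads_per_leaflet markers per leaflet per frame
#' @param dt frame interval, ns
#' @return an [ion_trajectory()] of zero-valence beads (species `HGU`/`HGL`)
#' @export
simulate_membrane_beads <- function(spec, n_frames = 20,
                                    beads_per_leaflet = 2000, dt = 1) {
  stopifnot(inherits(spec, "membrane_field_spec"))
  set.seed(spec$seed + 1L)
  nb <- 2L * beads_per_leaflet
  coords <- array(NA_real_, c(n_frames, nb, 3))
  surf <- function(x, y, sgn) {
    d2 <- (x - spec$center[1])^2 + (y - spec$center[2])^2
    u <- spec$u0 * exp(-d2 / (2 * spec$sigma^2))
    sgn * (spec$t_bulk / 2 - u)
  }
  for (f in seq_len(n_frames)) {
    x <- stats::runif(nb, 0, spec$grid_extent[1])
    y <- stats::runif(nb, 0, spec$grid_extent[2])
    sgn <- rep(c(1, -1), each = beads_per_leaflet)
    z <- surf(x, y, sgn) + stats::rnorm(nb, 0, spec$noise_sd)
    coords[f, , ] <- cbind(x, y, z)
  }
  ion_trajectory(coords, ids = seq_len(nb),
                 species = rep(c("HGU", "HGL"), each = beads_per_leaflet),
                 valence = rep(0L, nb),
                 box = c(spec$grid_extent, 3 * spec$t_bulk),
                 dt = dt,
                 metadata = list(ground_truth = list(spec = spec)))
}

#' Specification of a two-state (bound/unbound) binding process
#'
#' @param k_on pseudo-first-order binding rate, 1/ns
#' @param k_off unbinding rate, 1/ns
#' @param duration total time, ns
#' @param dt frame interval, ns; must satisfy `dt * max(k_on, k_off) < 0.1`
#' @param n_sites number of independent sites
#' @param seed integer RNG seed
#' @export
binding_spec <- function(k_on, k_off, duration, dt, n_sites = 1L, seed = 1L) {
  if (k_on <= 0 || k_off <= 0) stop("rates must be > 0")
  if (dt * max(k_on, k_off) >= 0.1)
    stop("dt too coarse: dt * max(k_on, k_off) must be < 0.1")
  structure(list(k_on = k_on, k_off = k_off, duration = duration, dt = dt,
                 n_sites = as.integer(n_sites), seed = as.integer(seed)),
            class = "binding_spec")
}

#' Simulate bound/unbound contact series as a two-state Markov chain
#'
#' Transition probabilities per frame are `1 - exp(-k dt)`; the stationary
#' occupancy is `k_on / (k_on + k_off)`. Initial states are drawn from the
#' stationary distribution.
#'
#' @param spec a [binding_spec()]
#' @return a [contact_series()] with the generating rates in `$meta`
#' @export
simulate_binding_series <- function(spec) {
  stopifnot(inherits(spec, "binding_spec"))
  set.seed(spec$seed)
  nfr <- max(2L, floor(spec$duration / spec$dt))
  p_on <- 1 - exp(-spec$k_on * spec$dt)
  p_off <- 1 - exp(-spec$k_off * spec$dt)
  pi_b <- spec$k_on / (spec$k_on + spec$k_off)
  ns <- spec$n_sites
  bound <- matrix(FALSE, ns, nfr)
  state <- stats::runif(ns) < pi_b
  bound[, 1] <- state
  for (f in 2:nfr) {
    u <- stats::runif(ns)
    state <- ifelse(state, u >= p_off, u < p_on)
    bound[, f] <- state
  }
  contact_series(bound = bound, sites = paste0("site", seq_len(ns)),
                 dt = spec$dt,
                 meta = list(ground_truth = list(
                   k_on = spec$k_on, k_off = spec$k_off,
                   occupancy = 100 * pi_b)))
}

#' Specification of synthetic umbrella-sampling windows
#'
#' @param pmf vectorized function U(x), kcal/mol
#' @param centers strictly increasing window centers, nm
#' @param k_umb umbrella force constant, kJ/mol/nm^2 (the MD engine's usual
#'   unit; converted internally)
#' @param n_samples samples per window
#' @param T temperature, K
#' @param seed integer RNG seed
#' @export
umbrella_spec <- function(pmf, centers, k_umb, n_samples = 2000, T = 300,
                          seed = 1L) {
  if (any(diff(centers) <= 0)) stop("centers must be strictly increasing")
  if (k_umb <= 0) stop("k_umb must be > 0")
  structure(list(pmf = pmf, centers = centers, k_umb = k_umb,
                 n_samples = as.integer(n_samples), T = T,
                 seed = as.integer(seed)),
            class = "umbrella_spec")
}

#' Draw samples from biased umbrella windows by rejection sampling
#'
#' Each window's samples follow the density proportional to
#' `exp(-beta [U(x) + k/2 (x - c)^2])`. The Gaussian defined by the bias
#' alone is the proposal; acceptance probability is
#' `exp(-beta (U(x) - U_min))` with `U_min` taken over the proposal's 6
#' sigma range, which makes the draw exact. Acceptance rates are recorded.
#'
#' @param spec an [umbrella_spec()]
#' @return list of `umbrella_window` objects (center, k_umb, samples, T,
#'   accept_rate)
#' @export
sample_umbrella_windows <- function(spec) {
  stopifnot(inherits(spec, "umbrella_spec"))
  set.seed(spec$seed)
  kT <- kt_kcal(spec$T)
  k_kcal <- spec$k_umb / 4.184
  s <- sqrt(kT / k_kcal)
  lapply(seq_along(spec$centers), function(i) {
    ctr <- spec$centers[i]
    xs <- seq(ctr - 6 * s, ctr + 6 * s, length.out = 512)
    u_min <- min(spec$pmf(xs))
    out <- numeric(0)
    tried <- 0L
    while (length(out) < spec$n_samples && tried < 1000L * spec$n_samples) {
      m <- 4L * spec$n_samples
      x <- stats::rnorm(m, ctr, s)
      acc <- stats::runif(m) < exp(-(spec$pmf(x) - u_min) / kT)
      out <- c(out, x[acc])
      tried <- tried + m
    }
    if (length(out) == 0L)
      stop(sprintf("sampling error: window %d (center %.3g) accepted no samples",
                   i, ctr))
    structure(list(center = ctr, k_umb = spec$k_umb,
                   samples = out[seq_len(min(length(out), spec$n_samples))],
                   T = spec$T,
                   accept_rate = length(out) / tried),
              class = "umbrella_window")
  })
}
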