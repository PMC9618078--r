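#' Minimal pore-radius profile of a static structure
#'
#' Per axial slice, the pore radius is the largest sphere centered in the
#' slice plane that touches no atom:
#' `radius(z) = max over (x,y) of min_i(|p - x_i| - R_i)`, found by a
#' deterministic Nelder-Mead search seeded from the previous slice's center
#' (the first slice from the geometric pore center). Arbitrary pore axes
#' are handled by rotating the structure so the axis maps to z.
#'
#' @param coords numeric matrix `[n_atoms, 3]`, nm
#' @param radii atomic radii, nm (recycled)
#' @param axis pore axis (unit vector not required; normalized internally)
#' @param z_range axial range c(lo, hi) in the rotated frame; default spans
#'   the structure
#' @param slice_dz slice spacing, nm
#' @param radius_cap radius assigned to open-pore slices where the search
#'   escapes the structure's bounding cylinder, nm
#' @return data.frame of class `pore_profile`: z, radius, cx, cy, flagged
#' @export
pore_radius_profile <- function(coords, radii, axis = c(0, 0, 1),
                                z_range = NULL, slice_dz = 0.1,
                                radius_cap = 5) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 4)
  radii <- rep_len(radii, nrow(coords))
  a <- axis / sqrt(sum(axis^2))
  R <- .rotation_to_z(a)
  xyz <- coords %*% t(R)
  if (is.null(z_range)) z_range <- range(xyz[, 3])
  zs <- seq(z_range[1], z_range[2], by = slice_dz)
  ctr <- c(mean(xyz[, 1]), mean(xyz[, 2]))
  r_bound <- max(sqrt((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2))
  seed <- ctr
  res <- lapply(zs, function(zsl) {
    obj <- function(p) {
      d <- sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 +
                  (xyz[, 3] - zsl)^2) - radii
      -min(d)
    }
    opt <- stats::optim(seed, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    ## restart once from the converged point (tightens the conical optimum)
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    p <- opt$par
    esc <- sqrt(sum((p - ctr)^2)) > r_bound
    if (!esc) seed <<- p
    data.frame(z = zsl,
               radius = if (esc) radius_cap else -opt$value,
               cx = p[1], cy = p[2], flagged = esc)
  })
  out <- do.call(rbind, res)
  class(out) <- c("pore_profile", class(out))
  out
}

## rotation matrix mapping unit vector a onto e_z (Rodrigues)
.rotation_to_z <- function(a) {
  ez <- c(0, 0, 1)
  v <- c(a[2] * ez[3] - a[3] * ez[2],
         a[3] * ez[1] - a[1] * ez[3],
         a[1] * ez[2] - a[2] * ez[1])
  c_ <- sum(a * ez)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))  # antiparallel
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Potential of mean force by the weighted histogram analysis method
#'
#' Standard WHAM self-consistent iteration over the unbiased probabilities
#' `P(x)` and window free energies `f_j` until `max |delta f_j|` drops
#' below `tolerance` (in kT) or `max_iter` is reached. The result is
#' referenced so the minimum over the bulk region is zero; if no bulk
#' region is given, the flattest 10%-of-span stretch of the profile's
#' outer quarters is used. Windows must overlap pairwise (adjacent
#' histograms sharing at least one occupied bin).
#'
#' A single window with zero bias reduces exactly to Boltzmann inversion
#' of its histogram.
#'
#' @param windows list of `umbrella_window` objects (center, k_umb in
#'   kJ/mol/nm^2, samples, T)
#' @param n_bins histogram bins over the pooled sample range (default 200,
#'   i.e. span/200 bin width)
#' @param tolerance convergence threshold on window free energies, kT
#' @param max_iter iteration cap
#' @param bulk_region optional c(lo, hi) reference interval, nm
#' @return a [pmf_profile()] on the bin centers
#' @export
wham_pmf <- function(windows, n_bins = 200, tolerance = 1e-6,
                     max_iter = 1e5, bulk_region = NULL) {
  stopifnot(length(windows) >= 1)
  T <- windows[[1]]$T %||% 300
  kT <- kt_kcal(T)
  beta <- 1 / kT
  allx <- unlist(lapply(windows, `[[`, "samples"))
  rng <- range(allx)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  nw <- length(windows)
  H <- matrix(0, nw, n_bins)
  for (j in seq_len(nw)) {
    h <- graphics::hist(windows[[j]]$samples, breaks = edges, plot = FALSE)
    H[j, ] <- h$counts
  }
  ## pairwise overlap check on windows ordered by center
  if (nw > 1) {
    ord <- order(vapply(windows, `[[`, numeric(1), "center"))
    occ <- H[ord, , drop = FALSE] > 0
    for (j in seq_len(nw - 1)) {
      if (!any(occ[j, ] & occ[j + 1, ]))
        stop(sprintf(paste0("connectivity error: windows centered at %.3g ",
                            "and %.3g nm share no occupied bin"),
                     windows[[ord[j]]]$center, windows[[ord[j + 1]]]$center))
    }
  }
  N <- rowSums(H)
  ntot <- colSums(H)
  ## bias energies, kcal/mol
  W <- matrix(0, nw, n_bins)
  for (j in seq_len(nw))
    W[j, ] <- 0.5 * windows[[j]]$k_umb / 4.184 *
      (mids - windows[[j]]$center)^2
  expW <- exp(-beta * W)
  f <- rep(0, nw)
  for (it in seq_len(max_iter)) {
    denom <- colSums(N * exp(beta * f) * expW)
    P <- ifelse(ntot > 0, ntot / denom, 0)
    fnew <- -kT * log(pmax(expW %*% P, .Machine$double.xmin))[, 1]
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tolerance * kT) break
  }
  if (delta >= tolerance * kT)
    stop(sprintf("iteration error: WHAM did not converge in %d iterations (residual %.3g kT)",
                 max_iter, delta / kT))
  F_ <- ifelse(P > 0, -kT * log(P), NA_real_)
  .reference_pmf(mids, F_, bulk_region)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## subtract the bulk reference: min over bulk_region = 0; if none given,
## pick the flattest 10%-of-span stretch within the outer quarters
.reference_pmf <- function(coord, energy, bulk_region = NULL) {
  ok <- is.finite(energy)
  if (!any(ok)) stop("reference error: profile has no sampled bins")
  if (is.null(bulk_region)) {
    span <- diff(range(coord))
    wlen <- max(3L, ceiling(0.1 * sum(ok)))
    outer_q <- coord <= stats::quantile(coord, 0.25) |
      coord >= stats::quantile(coord, 0.75)
    idx <- which(ok & outer_q)
    if (length(idx) < wlen) idx <- which(ok)
    best <- NULL; best_var <- Inf
    for (s in seq_len(length(idx) - wlen + 1L)) {
      w <- idx[s:(s + wlen - 1L)]
      if (any(diff(w) != 1L)) next
      v <- stats::var(energy[w])
      if (v < best_var) { best_var <- v; best <- w }
    }
    if (is.null(best)) best <- idx
    ref <- min(energy[best])
    bulk_region <- range(coord[best])
  } else {
    inb <- ok & coord >= bulk_region[1] & coord <= bulk_region[2]
    if (!any(inb)) stop("reference error: bulk region contains no sampled bins")
    ref <- min(energy[inb])
  }
  pmf_profile(coord, energy - ref, bulk_region = bulk_region)
}

#' Potential of mean force by Boltzmann inversion of an unbiased density
#'
#' `F(z) = -kT ln(rho / rho_bulk)` with the bulk density taken as the mean
#' over the bulk region. Empty bins are masked (NA), never +/-Inf.
#'
#' @param z bin centers, nm
#' @param density nonnegative ion counts or densities per bin
#' @param bulk_region c(lo, hi) reference interval, nm
#' @param T temperature, K
#' @return a [pmf_profile()]
#' @export
boltzmann_invert <- function(z, density, bulk_region, T = 300) {
  stopifnot(length(z) == length(density))
  if (any(density < 0)) stop("density must be nonnegative")
  inb <- z >= bulk_region[1] & z <= bulk_region[2]
  if (!any(inb) || mean(density[inb]) <= 0)
    stop("reference error: bulk region empty or unoccupied")
  kT <- kt_kcal(T)
  rho_b <- mean(density[inb])
  F_ <- ifelse(density > 0, -kT * log(density / rho_b), NA_real_)
  ## re-reference so the minimum over the bulk region is exactly 0
  F_ <- F_ - min(F_[inb], na.rm = TRUE)
  pmf_profile(z, F_, bulk_region = bulk_region)
}

#' Extract barriers and wells from a free-energy profile
#'
#' Per labeled axial region, reports the maximum (barrier) and minimum
#' (well) with their coordinates; the global maximum across the profile is
#' labeled as the primary barrier, and wells are returned sorted by depth
#' (most negative first).
#'
#' @param pmf a [pmf_profile()] (bulk-referenced)
#' @param regions named list of c(lo, hi) intervals, nm; default one region
#'   spanning the profile
#' @return list: `features` (data.frame region, barrier, barrier_z, well,
#'   well_z), `primary` (height, z), `wells` (sorted data.frame)
#' @export
profile_features <- function(pmf, regions = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  z <- pmf$coord; e <- pmf$energy
  if (is.null(regions)) regions <- list(all = range(z))
  rows <- lapply(names(regions), function(nm) {
    rg <- regions[[nm]]
    if (rg[1] > max(z) || rg[2] < min(z))
      stop("range error: region '", nm, "' lies outside the profile grid")
    i <- which(z >= rg[1] & z <= rg[2] & is.finite(e))
    if (!length(i))
      return(data.frame(region = nm, barrier = NA_real_, barrier_z = NA_real_,
                        well = NA_real_, well_z = NA_real_))
    hi <- i[which.max(e[i])]; lo <- i[which.min(e[i])]
    data.frame(region = nm, barrier = e[hi], barrier_z = z[hi],
               well = e[lo], well_z = z[lo])
  })
  feats <- do.call(rbind, rows)
  ok <- is.finite(e)
  gi <- which(ok)[which.max(e[ok])]
  wells <- feats[order(feats$well), c("region", "well", "well_z")]
  list(features = feats,
       primary = c(height = e[gi], z = z[gi]),
       wells = wells)
}
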