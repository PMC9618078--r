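#' Contact series container
#'
#' Residue/site by frame boolean bound record underlying occupancy,
#' residence-time and site-map statistics.
#'
#' @param bound logical matrix `[n_sites, n_frames]`
#' @param sites site labels
#' @param dt frame interval, ns
#' @param meta list of contact-definition metadata (cutoffs, selections)
#' @export
contact_series <- function(bound, sites, dt, meta = list()) {
  bound <- as.matrix(bound)
  if (nrow(bound) != length(sites))
    stop("bound matrix must have one row per site")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(bound = bound, sites = as.character(sites), dt = dt,
                 meta = meta), class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("contact_series: %d sites x %d frames (dt = %g ns)\n",
              nrow(x$bound), ncol(x$bound), x$dt))
  invisible(x)
}

#' Ligand-site contact series with dual-cutoff hysteresis
#'
#' A site becomes bound at the first frame any ligand bead lies within
#' `cutoff_on` of any site bead, and stays bound until the first frame all
#' ligand beads lie beyond `cutoff_off` (hysteresis debouncing, the
#' coarse-grained occupancy/residence convention; set
#' `cutoff_off = cutoff_on` for single-cutoff atomistic use). A site is
#' one species label among `site_species`; occupancy is any-ligand, not
#' same-ligand continuity. Distances are 3D with minimum-image wrapping.
#'
#' @param traj an [ion_trajectory()] containing ligand and site beads
#' @param ligand_species species labels treated as ligand beads
#' @param site_species species labels treated as sites (one site per label)
#' @param cutoff_on binding cutoff, nm
#' @param cutoff_off unbinding cutoff, nm (>= cutoff_on)
#' @return a [contact_series()]
#' @export
contact_series_from_traj <- function(traj, ligand_species, site_species,
                                     cutoff_on = 0.475, cutoff_off = 0.7) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (!(cutoff_off >= cutoff_on && cutoff_on > 0))
    stop("need cutoff_off >= cutoff_on > 0")
  il <- which(traj$species %in% ligand_species)
  if (!length(il)) stop("selection error: no ligand beads")
  sites <- intersect(unique(traj$species), site_species)
  if (!length(sites)) stop("selection error: no site beads")
  nf <- n_frames(traj)
  box <- traj$box[1, ]
  bound <- matrix(FALSE, length(sites), nf)
  dmin <- matrix(NA_real_, length(sites), nf)
  for (si in seq_along(sites)) {
    is_ <- which(traj$species == sites[si])
    for (f in seq_len(nf)) {
      dl <- traj$coords[f, il, , drop = FALSE]
      ds <- traj$coords[f, is_, , drop = FALSE]
      dd <- Inf
      for (a in seq_along(il)) {
        dv <- sweep(matrix(ds[1, , ], ncol = 3), 2, dl[1, a, ])
        dv <- dv - sweep(round(sweep(dv, 2, box, "/")), 2, box, "*")
        dd <- min(dd, sqrt(min(rowSums(dv^2))))
      }
      dmin[si, f] <- dd
    }
    b <- logical(nf)
    b[1] <- dmin[si, 1] <= cutoff_on
    for (f in 2:nf)
      b[f] <- dmin[si, f] <= cutoff_on ||
        (b[f - 1] && dmin[si, f] <= cutoff_off)
    bound[si, ] <- b
  }
  contact_series(bound, sites, traj$dt,
                 meta = list(cutoff_on = cutoff_on, cutoff_off = cutoff_off,
                             ligand_species = ligand_species, dmin = dmin))
}

#' Per-site percent occupancy
#'
#' @param series a [contact_series()]
#' @return named numeric vector, 100 x bound-frame fraction per site
#' @export
occupancy_map <- function(series) {
  stopifnot(inherits(series, "contact_series"))
  stats::setNames(100 * rowMeans(series$bound), series$sites)
}

#' Residence-time statistics per site
#'
#' Dwell lengths are taken from maximal bound intervals; intervals touching
#' either end of the series are censored and excluded. `k_off` is
#' estimated by a least-squares exponential fit to the empirical survival
#' curve of the dwell times.
#'
#' @param series a [contact_series()]
#' @return object of class `residence_stats`: `table` (data.frame site,
#'   n_dwell, mean_dwell_ns, k_off_per_ns) and `survival` (per-site list
#'   of data.frames t, S)
#' @export
residence_times <- function(series) {
  stopifnot(inherits(series, "contact_series"))
  nf <- ncol(series$bound)
  res <- lapply(seq_along(series$sites), function(si) {
    b <- series$bound[si, ]
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ib <- which(r$values)
    ## censor intervals touching the trajectory boundaries
    ib <- ib[starts[ib] > 1L & ends[ib] < nf]
    dw <- r$lengths[ib] * series$dt
    if (!length(dw))
      return(list(row = data.frame(site = series$sites[si], n_dwell = 0L,
                                   mean_dwell_ns = NA_real_,
                                   k_off_per_ns = NA_real_),
                  surv = NULL))
    ts <- sort(unique(dw))
    S <- vapply(ts, function(t) mean(dw >= t), numeric(1))
    pos <- S > 0
    k <- if (sum(pos) >= 2) {
      -stats::coef(stats::lm(log(S[pos]) ~ ts[pos]))[2]
    } else 1 / mean(dw)
    list(row = data.frame(site = series$sites[si], n_dwell = length(dw),
                          mean_dwell_ns = mean(dw),
                          k_off_per_ns = unname(k)),
         surv = data.frame(t = ts, S = S))
  })
  structure(list(table = do.call(rbind, lapply(res, `[[`, "row")),
                 survival = stats::setNames(lapply(res, `[[`, "surv"),
                                            series$sites)),
            class = "residence_stats")
}

#' @export
print.residence_stats <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Time-averaged 2D ligand density map within an axial slab
#'
#' Histograms ligand positions in the membrane plane for frames where the
#' ligand lies inside the z slab, normalized per frame so the map's total
#' mass equals the mean in-slab ligand count.
#'
#' @param traj an [ion_trajectory()] (one marker particle per ligand)
#' @param ligand_species species labels of the ligand markers
#' @param z_slab c(lo, hi), nm
#' @param grid_spacing cell size, nm
#' @return object of class `density_map_2d`: x, y, density matrix, slab,
#'   n_frames
#' @export
density_map_2d <- function(traj, ligand_species, z_slab, grid_spacing = 0.2) {
  stopifnot(inherits(traj, "ion_trajectory"))
  box <- traj$box[1, ]
  if (z_slab[1] >= z_slab[2])
    stop("z_slab must be an increasing interval")
  il <- which(traj$species %in% ligand_species)
  if (!length(il)) stop("selection error: no ligand particles")
  nx <- max(1L, round(box[1] / grid_spacing))
  ny <- max(1L, round(box[2] / grid_spacing))
  xb <- seq(0, box[1], length.out = nx + 1L)
  yb <- seq(0, box[2], length.out = ny + 1L)
  dens <- matrix(0, nx, ny)
  nf <- n_frames(traj)
  n_in <- 0L
  for (f in seq_len(nf)) {
    z <- traj$coords[f, il, 3]
    ins <- z >= z_slab[1] & z <= z_slab[2]
    if (!any(ins)) next
    n_in <- n_in + sum(ins)
    ix <- pmin(pmax(findInterval(traj$coords[f, il[ins], 1], xb,
                                 rightmost.closed = TRUE), 1L), nx)
    iy <- pmin(pmax(findInterval(traj$coords[f, il[ins], 2], yb,
                                 rightmost.closed = TRUE), 1L), ny)
    for (k in seq_along(ix)) dens[ix[k], iy[k]] <- dens[ix[k], iy[k]] + 1
  }
  if (n_in == 0L) warning("empty map: no ligand frames inside the slab")
  dens <- dens / nf
  structure(list(x = (xb[-1] + xb[-length(xb)]) / 2,
                 y = (yb[-1] + yb[-length(yb)]) / 2,
                 density = dens, slab = z_slab, n_frames = nf),
            class = "density_map_2d")
}

#' Joint distribution of ligand distances to two sites
#'
#' Per frame and ligand marker, the distances to the centers of mass of
#' two site selections are histogrammed jointly; the modal bin is
#' reported, flagged unstable when the mode carries little more mass than
#' the background (max density < 3x the mean occupied density).
#'
#' @param traj an [ion_trajectory()]
#' @param ligand_species ligand marker species
#' @param siteA_species,siteB_species species labels of the two site bead
#'   groups
#' @param bins number of bins per axis
#' @return object of class `pair_distance_hist`: `dA`, `dB` (bin centers),
#'   `counts`, `mode` c(dA, dB), `mode_unstable`
#' @export
pair_distance_hist2d <- function(traj, ligand_species, siteA_species,
                                 siteB_species, bins = 50) {
  stopifnot(inherits(traj, "ion_trajectory"))
  il <- which(traj$species %in% ligand_species)
  iA <- which(traj$species %in% siteA_species)
  iB <- which(traj$species %in% siteB_species)
  if (!length(il) || !length(iA) || !length(iB))
    stop("selection error: ligand and both sites must be present")
  nf <- n_frames(traj)
  dA <- dB <- numeric(0)
  for (f in seq_len(nf)) {
    comA <- colMeans(matrix(traj$coords[f, iA, ], ncol = 3))
    comB <- colMeans(matrix(traj$coords[f, iB, ], ncol = 3))
    for (a in il) {
      p <- traj$coords[f, a, ]
      dA <- c(dA, sqrt(sum((p - comA)^2)))
      dB <- c(dB, sqrt(sum((p - comB)^2)))
    }
  }
  ra <- range(dA); rb <- range(dB)
  if (diff(ra) == 0) ra <- ra + c(-0.05, 0.05)
  if (diff(rb) == 0) rb <- rb + c(-0.05, 0.05)
  ea <- seq(ra[1], ra[2], length.out = bins + 1L)
  eb <- seq(rb[1], rb[2], length.out = bins + 1L)
  ia <- pmin(pmax(findInterval(dA, ea, rightmost.closed = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(dB, eb, rightmost.closed = TRUE), 1L), bins)
  cnt <- matrix(0, bins, bins)
  for (k in seq_along(ia)) cnt[ia[k], ib[k]] <- cnt[ia[k], ib[k]] + 1
  mi <- which(cnt == max(cnt), arr.ind = TRUE)[1, ]
  ## heuristic: the mode is called unstable when its bin carries < 5% of
  ## the total mass (diffuse distribution rather than a defined pose)
  structure(list(dA = (ea[-1] + ea[-length(ea)]) / 2,
                 dB = (eb[-1] + eb[-length(eb)]) / 2,
                 counts = cnt,
                 mode = c(dA = (ea[mi[1]] + ea[mi[1] + 1]) / 2,
                          dB = (eb[mi[2]] + eb[mi[2] + 1]) / 2),
                 mode_unstable = max(cnt) < 0.05 * sum(cnt)),
            class = "pair_distance_hist")
}

#' Per-frame ion coordination numbers by partner class
#'
#' Counts partner particles strictly within the first-shell cutoff of each
#' tracked ion, split by partner class (e.g. water oxygens vs protein
#' oxygens), with the ion's axial position carried along so coordination
#' can be summarized against the pore coordinate.
#'
#' @param traj an [ion_trajectory()]
#' @param ion_species species labels of the tracked ions
#' @param partner_selections named list of species-label vectors, one per
#'   partner class
#' @param cutoffs named first-shell cutoffs per ion species, nm (defaults:
#'   Na 0.32, K 0.36, Ca 0.30 -- typical first minima of ion-oxygen radial
#'   distribution functions; configurable, not literature-fitted here)
#' @return data.frame: frame, ion_id, species, z, one count column per
#'   partner class
#' @export
coordination_numbers <- function(traj, ion_species, partner_selections,
                                 cutoffs = c(Na = 0.32, K = 0.36,
                                             Ca = 0.30)) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (any(cutoffs <= 0)) stop("cutoffs must be > 0")
  ii <- which(traj$species %in% ion_species)
  if (!length(ii)) stop("selection error: no tracked ions")
  box <- traj$box[1, ]
  part_idx <- lapply(partner_selections,
                     function(sp) which(traj$species %in% sp))
  nf <- n_frames(traj)
  rows <- list()
  for (f in seq_len(nf)) {
    for (i in ii) {
      rc <- cutoffs[traj$species[i]]
      if (is.na(rc)) stop("no cutoff given for species ", traj$species[i])
      p <- traj$coords[f, i, ]
      row <- data.frame(frame = f - 1L, ion_id = traj$ids[i],
                        species = traj$species[i], z = p[3])
      for (cls in names(part_idx)) {
        jp <- setdiff(part_idx[[cls]], i)
        if (!length(jp)) { row[[cls]] <- 0L; next }
        dv <- sweep(matrix(traj$coords[f, jp, ], ncol = 3), 2, p)
        dv <- dv - sweep(round(sweep(dv, 2, box, "/")), 2, box, "*")
        row[[cls]] <- sum(sqrt(rowSums(dv^2)) < rc)   # strict <
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
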