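#' Gridded leaflet surface container
#'
#' @param x,y cell-center coordinates, nm
#' @param upper,lower leaflet height matrices `[length(x), length(y)]`, nm
#' @param mask logical matrix of valid cells
#' @param counts optional per-leaflet bead-count matrices
#' @param ground_truth optional list (set by the synthetic generator)
#' @export
membrane_surface_grid <- function(x, y, upper, lower, mask,
                                  counts = NULL, ground_truth = NULL) {
  stopifnot(all(dim(upper) == c(length(x), length(y))),
            all(dim(lower) == dim(upper)), all(dim(mask) == dim(upper)))
  if (any(upper[mask] <= lower[mask], na.rm = TRUE))
    stop("upper leaflet must lie above the lower leaflet on masked cells")
  structure(list(x = x, y = y, upper = upper, lower = lower, mask = mask,
                 counts = counts, ground_truth = ground_truth),
            class = "membrane_surface_grid")
}

#' @export
print.membrane_surface_grid <- function(x, ...) {
  th <- thickness(x)
  cat(sprintf("membrane_surface_grid: %d x %d cells (%.0f%% masked in), thickness %.3g-%.3g nm\n",
              length(x$x), length(x$y), 100 * mean(x$mask),
              min(th, na.rm = TRUE), max(th, na.rm = TRUE)))
  invisible(x)
}

#' @rdname membrane_surface_grid
#' @param grid a `membrane_surface_grid`
#' @return matrix of bilayer thickness (nm), NA off-mask
#' @export
thickness <- function(grid) {
  th <- grid$upper - grid$lower
  th[!grid$mask] <- NA_real_
  th
}

#' Time-averaged membrane thickness map from headgroup marker beads
#'
#' Assigns each bead to a leaflet by its position relative to the
#' instantaneous membrane midplane (the frame's mean bead height), bins
#' beads on a regular (x, y) grid, time-averages per-cell leaflet heights,
#' optionally smooths with a Gaussian kernel, and masks cells with fewer
#' than `min_count` beads in either leaflet.
#'
#' @param traj an [ion_trajectory()] restricted to headgroup markers
#' @param grid_spacing cell size, nm
#' @param smoothing_sigma Gaussian smoothing width, nm (0 = none)
#' @param min_count minimum beads per leaflet per cell
#' @return a [membrane_surface_grid()]
#' @export
thickness_map <- function(traj, grid_spacing = 0.5, smoothing_sigma = 0,
                          min_count = 1L) {
  stopifnot(inherits(traj, "ion_trajectory"))
  Lx <- traj$box[1, 1]; Ly <- traj$box[1, 2]
  nx <- max(1L, round(Lx / grid_spacing))
  ny <- max(1L, round(Ly / grid_spacing))
  xb <- seq(0, Lx, length.out = nx + 1L)
  yb <- seq(0, Ly, length.out = ny + 1L)
  sum_u <- matrix(0, nx, ny); cnt_u <- matrix(0, nx, ny)
  sum_l <- matrix(0, nx, ny); cnt_l <- matrix(0, nx, ny)
  for (f in seq_len(n_frames(traj))) {
    x <- traj$coords[f, , 1]; y <- traj$coords[f, , 2]
    z <- traj$coords[f, , 3]
    mid <- mean(z)
    ix <- pmin(pmax(findInterval(x, xb, rightmost.closed = TRUE), 1L), nx)
    iy <- pmin(pmax(findInterval(y, yb, rightmost.closed = TRUE), 1L), ny)
    up <- z > mid
    idx <- cbind(ix, iy)
    for (leaf in c(TRUE, FALSE)) {
      sel <- up == leaf
      if (!any(sel)) next
      agg <- rowsum(cbind(z[sel], 1), group = (ix[sel] - 1L) * ny + iy[sel])
      cells <- as.integer(rownames(agg))
      ci <- cbind((cells - 1L) %/% ny + 1L, (cells - 1L) %% ny + 1L)
      if (leaf) {
        sum_u[ci] <- sum_u[ci] + agg[, 1]; cnt_u[ci] <- cnt_u[ci] + agg[, 2]
      } else {
        sum_l[ci] <- sum_l[ci] + agg[, 1]; cnt_l[ci] <- cnt_l[ci] + agg[, 2]
      }
    }
  }
  if (all(cnt_u == 0) || all(cnt_l == 0))
    stop("leaflet error: a leaflet received no beads")
  upper <- ifelse(cnt_u > 0, sum_u / cnt_u, NA_real_)
  lower <- ifelse(cnt_l > 0, sum_l / cnt_l, NA_real_)
  mask <- cnt_u >= min_count & cnt_l >= min_count
  if (smoothing_sigma > 0) {
    upper <- .gauss_blur(upper, smoothing_sigma / grid_spacing)
    lower <- .gauss_blur(lower, smoothing_sigma / grid_spacing)
  }
  xc <- (xb[-1] + xb[-length(xb)]) / 2
  yc <- (yb[-1] + yb[-length(yb)]) / 2
  membrane_surface_grid(xc, yc, upper, lower, mask & is.finite(upper) &
                          is.finite(lower),
                        counts = list(upper = cnt_u, lower = cnt_l))
}

## separable NA-aware Gaussian blur; sigma in cells
.gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  w <- !is.na(m)
  m0 <- ifelse(w, m, 0)
  conv1 <- function(mat, kern, along_rows) {
    n <- if (along_rows) nrow(mat) else ncol(mat)
    out <- matrix(0, nrow(mat), ncol(mat))
    for (o in seq_along(kern)) {
      sh <- o - r - 1L
      src <- pmin(pmax(seq_len(n) + sh, 1L), n)  # clamp at edges
      out <- out + kern[o] * (if (along_rows) mat[src, , drop = FALSE]
                              else mat[, src, drop = FALSE])
    }
    out
  }
  num <- conv1(conv1(m0, k, TRUE), k, FALSE)
  den <- conv1(conv1(w * 1, k, TRUE), k, FALSE)
  ifelse(den > 1e-12, num / den, NA_real_)
}

#' Ring-averaged radial thickness profile
#'
#' Averages the thickness map over concentric rings around `center` and
#' reports the recovery radius: the smallest radius beyond which the
#' profile stays within `tolerance` of the bulk thickness.
#'
#' @param map a [membrane_surface_grid()]
#' @param center 2D point, nm
#' @param dr ring width, nm
#' @param t_bulk bulk thickness, nm; default: mean thickness over the
#'   outermost rings
#' @param tolerance recovery tolerance, nm
#' @return data.frame (r, thickness, n_cells) with attributes
#'   `recovery_radius` and `t_bulk`
#' @export
radial_thickness_profile <- function(map, center, dr = 0.25, t_bulk = NULL,
                                     tolerance = 0.05) {
  th <- thickness(map)
  d <- sqrt(outer((map$x - center[1])^2, (map$y - center[2])^2, "+"))
  ok <- is.finite(th)
  rmax <- max(d[ok])
  edges <- seq(0, rmax + dr, by = dr)
  ring <- findInterval(d[ok], edges)
  prof <- data.frame(
    r = (edges[-1] + edges[-length(edges)]) / 2,
    thickness = as.numeric(tapply(th[ok], factor(ring,
      levels = seq_len(length(edges) - 1L)), mean)),
    n_cells = as.integer(table(factor(ring,
      levels = seq_len(length(edges) - 1L))))
  )
  if (is.null(t_bulk)) {
    outer_r <- prof$r >= 0.8 * rmax & prof$n_cells > 0
    t_bulk <- stats::weighted.mean(prof$thickness[outer_r],
                                   prof$n_cells[outer_r], na.rm = TRUE)
  }
  dev_ok <- is.na(prof$thickness) | abs(prof$thickness - t_bulk) < tolerance
  rec <- NA_real_
  for (i in seq_len(nrow(prof))) {
    if (all(dev_ok[i:nrow(prof)])) { rec <- prof$r[i]; break }
  }
  attr(prof, "recovery_radius") <- rec
  attr(prof, "t_bulk") <- t_bulk
  prof
}

#' Membrane compression free-energy penalty
#'
#' Quadratic leaflet-compression penalty
#' `G = (K_A / 2) * sum_cells (u / l)^2 * S_cell`, where `u` is the
#' per-leaflet deformation from the unperturbed leaflet thickness
#' (`u = (thickness - t_bulk) / 2`, both leaflets assumed symmetric),
#' `l = t_bulk / 2`, and `S_cell` is the cell area. Cells off the mask
#' (e.g. under the protein footprint, where no lipid reference beads
#' exist) are excluded. With `per_leaflet = TRUE` the two leaflets'
#' deformations are computed separately and their penalties averaged.
#'
#' @param map a [membrane_surface_grid()]
#' @param t_bulk unperturbed bilayer thickness, nm
#' @param K_A area stretch modulus, kT/nm^2 (default 60)
#' @param T temperature for the kcal/mol conversion, K
#' @param per_leaflet treat leaflets asymmetrically
#' @return object of class `compression_result`: `G_kT`, `G_kcal`,
#'   `per_cell` (kT contribution map), `params`
#' @export
compression_penalty <- function(map, t_bulk, K_A = 60, T = 300,
                                per_leaflet = FALSE) {
  stopifnot(inherits(map, "membrane_surface_grid"))
  if (t_bulk <= 0) stop("t_bulk must be > 0")
  if (K_A <= 0) stop("parameter error: K_A must be > 0")
  l <- t_bulk / 2
  S <- mean(diff(map$x)) * mean(diff(map$y))
  if (per_leaflet) {
    uu <- map$upper - l
    ul <- -map$lower - l
    per_cell <- (K_A / 2) * ((uu / l)^2 + (ul / l)^2) / 2 * S
  } else {
    u <- (thickness(map) - t_bulk) / 2
    per_cell <- (K_A / 2) * (u / l)^2 * S
  }
  per_cell[!map$mask] <- 0
  per_cell[is.na(per_cell)] <- 0
  G <- sum(per_cell)
  structure(list(G_kT = G, G_kcal = G * kt_kcal(T), per_cell = per_cell,
                 params = list(K_A = K_A, l = l, t_bulk = t_bulk, T = T,
                               per_leaflet = per_leaflet)),
            class = "compression_result")
}

#' @export
print.compression_result <- function(x, ...) {
  cat(sprintf("compression penalty: %.4g kT = %.4g kcal/mol at %g K\n",
              x$G_kT, x$G_kcal, x$params$T))
  invisible(x)
}
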