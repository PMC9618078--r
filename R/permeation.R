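#' Unwrap axial tracks and flag teleports
#'
#' Converts wrapped per-particle axial coordinates into continuous tracks
#' using minimum-image displacements, and flags non-physical jumps
#' (computational-electrophysiology swaps) whose minimum-image displacement
#' is at least `jump_threshold * box_z`. A flagged step resets that
#' particle's unwrapped track (new segment) so downstream state machines
#' can restart cleanly.
#'
#' @param traj an [ion_trajectory()]
#' @param geometry a [channel_geometry()] (unused for the unwrap itself,
#'   kept for interface symmetry)
#' @param jump_threshold fraction of the box length, default 0.5
#' @return list with `z` (wrapped, frames x particles), `z_unwrapped`,
#'   `teleport` (logical, TRUE at frame f if the step f-1 -> f is a
#'   teleport), `times`, `box_z`
#' @export
unwrap_axial_tracks <- function(traj, geometry = NULL, jump_threshold = 0.5) {
  stopifnot(inherits(traj, "ion_trajectory"))
  z <- traj$coords[, , 3, drop = TRUE]
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  nf <- nrow(z)
  box_z <- traj$box[, 3]
  dz <- z[-1, , drop = FALSE] - z[-nf, , drop = FALSE]
  bz <- box_z[-1]
  dz_mi <- dz - bz * round(dz / bz)
  tele <- rbind(FALSE, abs(dz_mi) >= jump_threshold * bz)
  zu <- z
  for (p in seq_len(ncol(z))) {
    steps <- dz_mi[, p]
    tp <- which(tele[-1, p])
    zp <- numeric(nf)
    zp[1] <- z[1, p]
    cum <- cumsum(steps)
    zp[-1] <- z[1, p] + cum
    if (length(tp)) {
      ## restart each segment at the wrapped position after the teleport
      bounds <- c(tp + 1L, nf + 1L)
      for (k in seq_along(tp)) {
        f0 <- bounds[k]
        f1 <- bounds[k + 1L] - 1L
        off <- z[f0, p] - zp[f0]
        zp[f0:f1] <- zp[f0:f1] + off
      }
    }
    zu[, p] <- zp
  }
  list(z = z, z_unwrapped = zu, teleport = tele, times = frame_times(traj),
       box_z = box_z)
}

## crossings of plane P (and its periodic images) by an unwrapped track.
## Returns data.frame(frame, dir): dir +1 for upward (+z) crossings at step
## (frame-1 -> frame). Uses the floor-index trick: the integer
## floor((z - P)/L) changes exactly when an image of P is crossed.
.plane_crossings <- function(zu, P, L, periodic) {
  k <- if (periodic) floor((zu - P) / L) else as.integer(zu >= P)
  dk <- diff(k)
  f <- which(dk != 0) + 1L
  data.frame(frame = f, dir = sign(dk[f - 1L]))
}

#' Detect full channel traversals
#'
#' Runs a per-particle three-state machine over the unwrapped axial tracks:
#' a particle is outside, entered-from-outer, or entered-from-inner. An
#' event is recorded iff the particle passes beyond the far end plane
#' (`boundary_z - extent_in` or `boundary_z + extent_out`) after having
#' entered past the near end plane, and its radial distance from the
#' pathway axis was below `cyl_radius` at a boundary-plane crossing frame
#' in between. Teleport flags reset the state machine without emitting
#' events; a particle that starts inside the channel can complete at most a
#' half traversal and emits nothing. Direction +1 is outer-to-inner
#' (decreasing axial coordinate), matching the reporting convention stored
#' in the geometry.
#'
#' For a double-bilayer geometry the two antiparallel channel copies are
#' processed separately with consistent outer-to-inner orientation and the
#' events concatenated.
#'
#' @param traj an [ion_trajectory()]
#' @param geometry a [channel_geometry()]
#' @param tracks optional precomputed [unwrap_axial_tracks()] result
#' @param jump_threshold passed to [unwrap_axial_tracks()]
#' @param periodic treat the box as z-periodic (default TRUE)
#' @return data.frame with columns particle_id, species, valence, t_cross
#'   (ns, time of the boundary crossing), direction (+1/-1)
#' @export
detect_permeation_events <- function(traj, geometry, tracks = NULL,
                                     jump_threshold = 0.5, periodic = TRUE) {
  stopifnot(inherits(traj, "ion_trajectory"),
            inherits(geometry, "channel_geometry"))
  if (is.null(tracks))
    tracks <- unwrap_axial_tracks(traj, geometry, jump_threshold)
  box_z <- traj$box[1, 3]
  if (geometry$extent_out + geometry$extent_in > box_z)
    stop("configuration error: geometry extents exceed the box length")
  ev <- .detect_single(traj, tracks, geometry$boundary_z,
                       geometry$extent_out, geometry$extent_in,
                       geometry$cyl_radius, geometry$center_xy,
                       flip = FALSE, periodic = periodic)
  if (geometry$n_membranes == 2L) {
    ev2 <- .detect_single(traj, tracks, geometry$second_boundary_z,
                          geometry$extent_out, geometry$extent_in,
                          geometry$cyl_radius, geometry$center_xy,
                          flip = TRUE, periodic = periodic)
    ev <- rbind(ev, ev2)
  }
  ev <- ev[order(ev$t_cross), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

## single channel copy; flip = TRUE for the antiparallel copy (its
## extracellular side faces -z, so plane roles and signs invert)
.detect_single <- function(traj, tracks, boundary_z, extent_out, extent_in,
                           cyl_radius, center_xy, flip, periodic) {
  zu <- tracks$z_unwrapped
  tele <- tracks$teleport
  times <- tracks$times
  box_z <- traj$box[1, 3]
  box_xy <- traj$box[1, 1:2]
  outer_plane <- if (!flip) boundary_z + extent_out else boundary_z - extent_out
  inner_plane <- if (!flip) boundary_z - extent_in else boundary_z + extent_in
  ## upward crossing of the outer plane means leaving toward outer side for
  ## the unflipped copy; sign bookkeeping below is in terms of "toward
  ## outer" (+o) / "toward inner" (-o) with o = +1 unflipped, -1 flipped
  o <- if (!flip) 1 else -1
  out <- vector("list", ncol(zu))
  for (p in seq_len(ncol(zu))) {
    cr_o <- .plane_crossings(zu[, p], outer_plane, box_z, periodic)
    cr_b <- .plane_crossings(zu[, p], boundary_z, box_z, periodic)
    cr_i <- .plane_crossings(zu[, p], inner_plane, box_z, periodic)
    tp <- which(tele[, p])
    evs <- rbind(
      if (nrow(cr_o)) cbind(cr_o, plane = 1L) else NULL,
      if (nrow(cr_b)) cbind(cr_b, plane = 0L) else NULL,
      if (nrow(cr_i)) cbind(cr_i, plane = -1L) else NULL,
      if (length(tp)) data.frame(frame = tp, dir = 0L, plane = 9L) else NULL
    )
    if (is.null(evs) || nrow(evs) == 0L) next
    ## order: by frame; within a frame teleports first, then planes in the
    ## order they lie along the displacement direction
    plane_pos <- ifelse(evs$plane == 1L, outer_plane,
                        ifelse(evs$plane == 0L, boundary_z, inner_plane))
    along <- evs$dir * plane_pos
    evs <- evs[order(evs$frame, evs$plane != 9L, along), , drop = FALSE]
    state <- 0L   # 0 outside, +1 entered from outer, -1 entered from inner
    rad_ok <- FALSE
    t_b <- NA_real_
    res <- list()
    for (k in seq_len(nrow(evs))) {
      e <- evs[k, ]
      if (e$plane == 9L) { state <- 0L; rad_ok <- FALSE; next }
      inward <- (e$dir * o) < 0   # moving toward the inner side
      if (e$plane == 1L) {        # outer end plane
        if (state == 0L && inward) { state <- 1L; rad_ok <- FALSE; t_b <- NA }
        else if (state == -1L && !inward) {
          if (rad_ok) res[[length(res) + 1L]] <- c(t_b, -1)
          state <- 0L
        } else if (state == 1L && !inward) state <- 0L
      } else if (e$plane == -1L) { # inner end plane
        if (state == 0L && !inward) { state <- -1L; rad_ok <- FALSE; t_b <- NA }
        else if (state == 1L && inward) {
          if (rad_ok) res[[length(res) + 1L]] <- c(t_b, +1)
          state <- 0L
        } else if (state == -1L && inward) state <- 0L
      } else {                     # boundary plane
        if (state != 0L && !rad_ok) {
          f <- e$frame
          dxy <- traj$coords[f, p, 1:2] - center_xy
          dxy <- dxy - box_xy * round(dxy / box_xy)
          if (sqrt(sum(dxy^2)) < cyl_radius) { rad_ok <- TRUE; t_b <- times[f] }
        }
      }
    }
    if (length(res)) {
      m <- do.call(rbind, res)
      out[[p]] <- data.frame(particle_id = traj$ids[p],
                             species = traj$species[p],
                             valence = traj$valence[p],
                             t_cross = m[, 1], direction = m[, 2])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(particle_id = integer(), species = character(),
                      valence = integer(), t_cross = numeric(),
                      direction = numeric()))
  do.call(rbind, out)
}

#' Tally permeation events over time
#'
#' Cumulative signed per-species event counts on a regular time grid, plus
#' the total signed charge transferred (units of e). The cumulative count
#' is a step function changing by +/-1 per event.
#'
#' @param events data.frame from [detect_permeation_events()]
#' @param dt_grid grid spacing, ns
#' @param t_range c(t0, t1); defaults to the event span (or c(0, dt_grid)
#'   for an empty list)
#' @return object of class `event_tally`: `time`, `counts` (species x grid
#'   cumulative matrix), `charge_e`, and the (sorted) `events`
#' @export
tally_events <- function(events, dt_grid = 1, t_range = NULL) {
  events <- as.data.frame(events)
  if (nrow(events) && is.unsorted(events$t_cross))
    events <- events[order(events$t_cross), ]
  if (is.null(t_range)) {
    t_range <- if (nrow(events)) c(0, max(events$t_cross)) else c(0, dt_grid)
  }
  grid <- seq(t_range[1], t_range[2], by = dt_grid)
  if (grid[length(grid)] < t_range[2]) grid <- c(grid, t_range[2])
  sp <- sort(unique(as.character(events$species)))
  counts <- matrix(0, nrow = max(1L, length(sp)), ncol = length(grid),
                   dimnames = list(if (length(sp)) sp else "none", NULL))
  if (nrow(events)) {
    for (s in sp) {
      es <- events[events$species == s, ]
      counts[s, ] <- vapply(grid, function(t)
        sum(es$direction[es$t_cross <= t]), numeric(1))
    }
  }
  structure(list(time = grid, counts = counts,
                 charge_e = if (nrow(events))
                   sum(events$direction * events$valence) else 0,
                 events = events, t_range = t_range),
            class = "event_tally")
}

#' @export
print.event_tally <- function(x, ...) {
  cat(sprintf("event_tally: %d events over [%g, %g] ns, net charge %+g e\n",
              nrow(x$events), x$t_range[1], x$t_range[2], x$charge_e))
  if (nrow(x$events)) {
    fin <- x$counts[, ncol(x$counts)]
    cat("  cumulative by species:",
        paste(sprintf("%s %+g", rownames(x$counts), fin), collapse = ", "),
        "\n")
  }
  invisible(x)
}
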