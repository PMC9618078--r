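# Independent oracles used to cross-check the implementation. These scan
# trajectories exhaustively with naive logic and share no code with the
# package's detectors.

# exhaustive-scan permeation oracle (single channel copy, standard
# orientation): per particle, list every plane crossing chronologically,
# then scan the crossing string for (outer-entry ... radial-ok boundary
# crossing ... inner-exit) triples and their inner-entry mirror images.
oracle_scan_events <- function(traj, geometry, jump_threshold = 0.5) {
  z <- traj$coords[, , 3, drop = TRUE]
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  nf <- nrow(z)
  box_z <- traj$box[1, 3]
  box_xy <- traj$box[1, 1:2]
  times <- frame_times(traj)
  b <- geometry$boundary_z
  planes <- c(O = b + geometry$extent_out, B = b, I = b - geometry$extent_in)
  out <- list()
  for (p in seq_len(ncol(z))) {
    toks <- list()
    for (f in 2:nf) {
      dz <- z[f, p] - z[f - 1, p]
      dzm <- dz - box_z * round(dz / box_z)
      if (abs(dzm) >= jump_threshold * box_z) {
        toks[[length(toks) + 1]] <- list(f = f, lab = "R", dir = 0, pos = 0)
        next
      }
      z0 <- z[f - 1, p]; z1 <- z0 + dzm
      lohi <- sort(c(z0, z1))
      step_toks <- list()
      for (nm in names(planes)) {
        P <- planes[[nm]]
        for (k in seq(floor((lohi[1] - P) / box_z) - 1,
                      ceiling((lohi[2] - P) / box_z) + 1)) {
          pos <- P + k * box_z
          if (lohi[1] < pos && pos <= lohi[2] && z0 != z1) {
            step_toks[[length(step_toks) + 1]] <-
              list(f = f, lab = nm, dir = sign(dzm), pos = pos)
          }
        }
      }
      if (length(step_toks)) {
        ord <- order(vapply(step_toks, function(t) t$dir * t$pos, 0))
        toks <- c(toks, step_toks[ord])
      }
    }
    if (!length(toks)) next
    rad_ok <- function(f) {
      dxy <- traj$coords[f, p, 1:2] - geometry$center_xy
      dxy <- dxy - box_xy * round(dxy / box_xy)
      sqrt(sum(dxy^2)) < geometry$cyl_radius
    }
    labs <- vapply(toks, function(t) t$lab, "")
    dirs <- vapply(toks, function(t) t$dir, 0)
    i <- 1
    while (i <= length(toks)) {
      lab <- labs[i]; dir <- dirs[i]
      entry <- NULL
      if (lab == "O" && dir == -1) entry <- "outer"
      if (lab == "I" && dir == +1) entry <- "inner"
      if (is.null(entry)) { i <- i + 1; next }
      j <- i + 1
      done <- FALSE
      while (j <= length(toks) && !done) {
        lj <- labs[j]; dj <- dirs[j]
        if (lj == "R") { i <- j; done <- TRUE; break }
        complete <- (entry == "outer" && lj == "I" && dj == -1) ||
          (entry == "inner" && lj == "O" && dj == +1)
        abort <- (entry == "outer" && lj == "O" && dj == +1) ||
          (entry == "inner" && lj == "I" && dj == -1)
        if (complete) {
          bs <- which(labs[(i + 1):(j - 1)] == "B") + i
          tb <- NA_real_
          for (fb in bs) if (rad_ok(toks[[fb]]$f)) { tb <- times[toks[[fb]]$f]; break }
          if (!is.na(tb)) {
            out[[length(out) + 1]] <- data.frame(
              particle_id = traj$ids[p], species = traj$species[p],
              valence = traj$valence[p], t_cross = tb,
              direction = if (entry == "outer") 1 else -1)
          }
          i <- j; done <- TRUE
        } else if (abort) {
          i <- j; done <- TRUE
        } else j <- j + 1
      }
      if (!done) break
    }
  }
  if (!length(out))
    return(data.frame(particle_id = integer(), species = character(),
                      valence = integer(), t_cross = numeric(),
                      direction = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$t_cross), ]
  rownames(res) <- NULL
  res
}

# explicit hysteresis automaton over a minimum-distance series
oracle_hysteresis <- function(dmin, on, off) {
  b <- logical(length(dmin))
  state <- dmin[1] <= on
  b[1] <- state
  for (f in 2:length(dmin)) {
    if (!state && dmin[f] <= on) state <- TRUE
    else if (state && dmin[f] > off) state <- FALSE
    b[f] <- state
  }
  b
}

# canonical event key for set comparison
event_key <- function(ev) {
  if (!nrow(ev)) return(character(0))
  sort(sprintf("%d|%+d|%.6f", ev$particle_id, ev$direction, ev$t_cross))
}
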