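# ligand at prescribed distances from a single-bead site at the box center
dist_traj <- function(d, box = c(12, 12, 12)) {
  nf <- length(d)
  co <- array(NA_real_, c(nf, 2, 3))
  co[, 1, 1] <- 6; co[, 1, 2] <- 6; co[, 1, 3] <- 6          # site bead
  co[, 2, 1] <- 6 + d; co[, 2, 2] <- 6; co[, 2, 3] <- 6      # ligand bead
  ion_trajectory(co, 1:2, c("M253", "CHOL"), c(0L, 0L), box, dt = 1)
}

test_that("dual-cutoff contact series debounces flicker", {
  ## fixed 0.3 nm: bound every frame
  cs <- contact_series_from_traj(dist_traj(rep(0.3, 20)), "CHOL", "M253")
  expect_true(all(cs$bound))
  ## ramp 0.3 -> 1.0: single interval ending at the first frame > 0.7
  d <- seq(0.3, 1.0, length.out = 28)  # no point lands on a cutoff
  cs2 <- contact_series_from_traj(dist_traj(d), "CHOL", "M253")
  b <- cs2$bound[1, ]
  expect_identical(unname(b), d <= 0.7)
  expect_identical(sum(diff(b) != 0), 1L)
  ## flicker crossing 0.5 but never 0.7: one unbroken interval
  set.seed(2)
  df <- 0.55 + 0.12 * sin(seq(0, 20 * pi, length.out = 300))
  df[1] <- 0.4   # bind initially
  cs3 <- contact_series_from_traj(dist_traj(df), "CHOL", "M253")
  expect_true(all(cs3$bound))
  ## agreement with the explicit hysteresis automaton on a rough series
  dr <- runif(400, 0.2, 1.1)
  cs4 <- contact_series_from_traj(dist_traj(dr), "CHOL", "M253")
  expect_identical(unname(cs4$bound[1, ]),
                   oracle_hysteresis(dr, 0.475, 0.7))
  expect_error(contact_series_from_traj(dist_traj(dr), "CHOL", "none"),
               "selection error")
})

test_that("occupancy is the bound-frame percentage", {
  cs <- contact_series(matrix(c(TRUE, TRUE, FALSE, FALSE), 1), "s", dt = 1)
  expect_equal(unname(occupancy_map(cs)), 50)
  always <- contact_series(matrix(TRUE, 1, 10), "s", dt = 1)
  never <- contact_series(matrix(FALSE, 1, 10), "s", dt = 1)
  expect_equal(unname(occupancy_map(always)), 100)
  expect_equal(unname(occupancy_map(never)), 0)
  ## complement property
  comp <- contact_series(!cs$bound, "s", dt = 1)
  expect_equal(unname(occupancy_map(cs) + occupancy_map(comp)), 100)
})

test_that("the k_on/k_off = 3 regime resolves as 75% occupancy", {
  b <- binding_spec(k_on = 0.3, k_off = 0.1, duration = 10000, dt = 0.2,
                    n_sites = 3, seed = 6)
  cs <- simulate_binding_series(b)
  occ <- occupancy_map(cs)
  tau_c <- 1 / (b$k_on + b$k_off)
  sd_occ <- 100 * sqrt(0.75 * 0.25 * 2 * tau_c / b$duration)
  expect_true(all(abs(occ - 75) < 3 * sd_occ))
})

test_that("residence times recover dwell statistics", {
  ## deterministic alternating 10 ns bound / 10 ns unbound
  pat <- rep(c(rep(TRUE, 10), rep(FALSE, 10)), 20)
  cs <- contact_series(matrix(pat, 1), "s", dt = 1)
  rs <- residence_times(cs)
  expect_equal(rs$table$mean_dwell_ns, 10)
  ## a single unbroken interval spanning the series is censored
  cs1 <- contact_series(matrix(TRUE, 1, 100), "s", dt = 1)
  r1 <- residence_times(cs1)
  expect_identical(r1$table$n_dwell, 0L)
  expect_true(is.na(r1$table$k_off_per_ns))
  ## two-state generator: k_off within 20% at 1e4 ns
  b <- binding_spec(k_on = 0.3, k_off = 0.1, duration = 10000, dt = 0.2,
                    n_sites = 1, seed = 8)
  rs2 <- residence_times(simulate_binding_series(b))
  expect_lt(abs(rs2$table$k_off_per_ns / 0.1 - 1), 0.2)
})

test_that("2D density maps conserve in-slab mass", {
  ## ligand fixed at one (x, y) inside the slab: single cell of mass 1
  nf <- 4
  co <- array(NA_real_, c(nf, 1, 3))
  co[, 1, 1] <- 3.1; co[, 1, 2] <- 7.4; co[, 1, 3] <- 5
  traj <- ion_trajectory(co, 1L, "PNU", 0L, c(10, 10, 10), dt = 1)
  dm <- density_map_2d(traj, "PNU", z_slab = c(4, 6), grid_spacing = 0.5)
  expect_equal(sum(dm$density), 1)
  expect_identical(sum(dm$density > 0), 1L)
  ## ligand outside the slab: empty map with warning
  co[, 1, 3] <- 9
  t2 <- ion_trajectory(co, 1L, "PNU", 0L, c(10, 10, 10), dt = 1)
  expect_warning(d2 <- density_map_2d(t2, "PNU", c(4, 6)), "empty map")
  expect_true(all(d2$density == 0))
  ## five-fold symmetric ligands: five equal peaks where the oracle puts
  ## them, total mass = mean in-slab count
  th <- 2 * pi * (0:4) / 5
  co5 <- array(NA_real_, c(3, 5, 3))
  for (f in 1:3) co5[f, , ] <- cbind(5 + 2 * cos(th), 5 + 2 * sin(th), 5)
  t5 <- ion_trajectory(co5, 1:5, rep("PNU", 5), rep(0L, 5),
                       c(10, 10, 10), dt = 1)
  d5 <- density_map_2d(t5, "PNU", c(4, 6), grid_spacing = 0.5)
  expect_equal(sum(d5$density), 5, tolerance = 1e-9)
  peaks <- which(d5$density > 0, arr.ind = TRUE)
  expect_identical(nrow(peaks), 5L)
  expect_true(all(abs(d5$density[peaks] - 1) < 1e-12))
  ## oracle: direct histogram of one frame
  ix <- pmin(pmax(findInterval(5 + 2 * cos(th),
                               seq(0, 10, by = 0.5),
                               rightmost.closed = TRUE), 1), 20)
  iy <- pmin(pmax(findInterval(5 + 2 * sin(th),
                               seq(0, 10, by = 0.5),
                               rightmost.closed = TRUE), 1), 20)
  for (k in 1:5) expect_gt(d5$density[ix[k], iy[k]], 0)
})

test_that("pair-distance distributions locate binding poses", {
  ## ligand fixed 0.8 nm from site A and 0.5 nm from site B
  co <- array(NA_real_, c(3, 3, 3))
  co[, 1, ] <- matrix(rep(c(5, 5, 5), each = 3), 3)        # site A
  co[, 2, ] <- matrix(rep(c(5, 5 + 1.3, 5), each = 3), 3)  # site B
  co[, 3, ] <- matrix(rep(c(5, 5.8, 5), each = 3), 3)      # ligand
  traj <- ion_trajectory(co, 1:3, c("M253", "M278", "PNU"),
                         rep(0L, 3), c(10, 10, 10), dt = 1)
  ph <- pair_distance_hist2d(traj, "PNU", "M253", "M278", bins = 20)
  expect_equal(unname(ph$mode["dA"]), 0.8, tolerance = 0.05)
  expect_equal(unname(ph$mode["dB"]), 0.5, tolerance = 0.05)
  expect_false(ph$mode_unstable)
  ## two ligands at distinct poses: bimodal (two occupied cells)
  co2 <- array(NA_real_, c(3, 4, 3))
  co2[, 1:2, ] <- co[, 1:2, ]
  co2[, 3, ] <- matrix(rep(c(5, 5.8, 5), each = 3), 3)
  co2[, 4, ] <- matrix(rep(c(5, 4.6, 5), each = 3), 3)
  t2 <- ion_trajectory(co2, 1:4, c("M253", "M278", "PNU", "PNU"),
                       rep(0L, 4), c(10, 10, 10), dt = 1)
  p2 <- pair_distance_hist2d(t2, "PNU", "M253", "M278", bins = 15)
  expect_identical(sum(p2$counts > 0), 2L)
  ## diffuse ligand: unstable mode flag
  set.seed(11)
  nf <- 200
  co3 <- array(NA_real_, c(nf, 3, 3))
  co3[, 1, ] <- matrix(rep(c(5, 5, 5), each = nf), nf)
  co3[, 2, ] <- matrix(rep(c(5, 6.3, 5), each = nf), nf)
  co3[, 3, ] <- cbind(runif(nf, 2, 8), runif(nf, 2, 8), runif(nf, 2, 8))
  t3 <- ion_trajectory(co3, 1:3, c("A", "B", "L"), rep(0L, 3),
                       c(10, 10, 10), dt = 1)
  p3 <- pair_distance_hist2d(t3, "L", "A", "B", bins = 25)
  expect_true(p3$mode_unstable)
})

test_that("coordination numbers count strict first-shell partners", {
  ## octahedral shell at 0.24 nm around a Na ion
  shell <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)) * 0.24
  co <- array(NA_real_, c(2, 8, 3))
  for (f in 1:2) {
    co[f, 1, ] <- c(5, 5, 5)
    co[f, 2:7, ] <- sweep(shell, 2, c(5, 5, 5), "+")
    co[f, 8, ] <- c(5 + 0.32, 5, 5)   # exactly at the cutoff
  }
  traj <- ion_trajectory(co, 1:8, c("Na", rep("OW", 6), "OP"),
                         c(1L, rep(0L, 7)), c(10, 10, 10), dt = 1)
  cn <- coordination_numbers(traj, "Na",
                             list(water_O = "OW", protein_O = "OP"))
  expect_true(all(cn$water_O == 6))
  expect_true(all(cn$protein_O == 0))   # boundary partner excluded
  ## random gas: mean count = density * (4/3) pi r^3 within 3 sigma
  set.seed(13)
  nO <- 600; L <- 6; nf <- 30
  cog <- array(runif(nf * (nO + 1) * 3, 0, L), c(nf, nO + 1, 3))
  cog[, 1, ] <- L / 2
  tg <- ion_trajectory(cog, 1:(nO + 1), c("Na", rep("OW", nO)),
                       c(1L, rep(0L, nO)), c(L, L, L), dt = 1)
  cng <- coordination_numbers(tg, "Na", list(water_O = "OW"))
  lam <- nO / L^3 * (4 / 3) * pi * 0.32^3
  expect_lt(abs(mean(cng$water_O) - lam), 3 * sqrt(lam / nf))
})
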