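test_that("windowed currents convert event counts to pA", {
  ## 10 monovalent events uniform over 100 ns; every 20-ns window holds 2
  ## events: I = 2 e / 20 ns = 16.0218 pA
  ev <- data.frame(particle_id = 1:10, species = "Na", valence = 1L,
                   t_cross = seq(5, 95, by = 10), direction = 1)
  tl <- tally_events(ev, dt_grid = 1, t_range = c(0, 100))
  cs <- windowed_current(tl, window = 20, overlap = 10)
  expect_equal(nrow(cs), 9L)   # centers 10..90
  expect_equal(cs$current_pA, rep(16.02176634, 9), tolerance = 1e-9)
  ## zero events -> all-zero series
  cs0 <- windowed_current(tally_events(ev[0, ], t_range = c(0, 100)),
                          window = 20, overlap = 10, t_range = c(0, 100))
  expect_true(all(cs0$current_pA == 0))
  ## one Ca2+ event carries exactly twice the Na+ current
  ev2 <- data.frame(particle_id = 1:2, species = c("Ca", "Na"),
                    valence = c(2L, 1L), t_cross = c(5, 6), direction = 1)
  c2 <- windowed_current(tally_events(ev2, t_range = c(0, 20)),
                         window = 20, overlap = 10, t_range = c(0, 20))
  expect_equal(c2$I_Ca_pA, 2 * c2$I_Na_pA)
  ## too-long window falls back to a single window with warning
  expect_warning(windowed_current(tl, window = 500, overlap = 10),
                 "single window")
})

test_that("conductance fits recover an exact line with zero-width CI", {
  iv <- data.frame(V_mV = c(-200, -100, 0, 100, 200))
  iv$I_pA <- 0.0766 * iv$V_mV
  f <- fit_iv_conductance(iv)
  expect_equal(f$G_pS, 76.6, tolerance = 1e-9)
  expect_equal(f$ci95[1], f$ci95[2], tolerance = 1e-6)
  expect_equal(f$intercept_pA, 0, tolerance = 1e-9)
  ## subsets
  iv2 <- iv
  iv2$I_pA <- ifelse(iv2$V_mV > 0, 0.223 * iv2$V_mV, 0.0442 * iv2$V_mV)
  fd <- fit_iv_conductance(iv2, "depolarized")
  fp <- fit_iv_conductance(iv2, "polarized")
  expect_equal(fd$G_pS, 223.0, tolerance = 1e-9)
  expect_equal(fp$G_pS, 44.2, tolerance = 1e-9)
  ## the full-set slope lies between the subset slopes
  ff <- fit_iv_conductance(iv2, "full")
  expect_true(ff$G_pS > fp$G_pS && ff$G_pS < fd$G_pS)
  ## degenerate designs error out
  expect_error(fit_iv_conductance(data.frame(V_mV = c(0, 0, 0),
                                             I_pA = c(0, 1, 2))),
               "fit error")
})

test_that("slope CI has near-nominal coverage", {
  G_true <- 0.08  # pA/mV
  hits <- 0L
  set.seed(99)
  for (r in 1:100) {
    V <- rep(c(-200, -100, -50, 50, 100, 200), length.out = 40)
    iv <- data.frame(V_mV = V, I_pA = G_true * V + rnorm(40, 0, 3))
    f <- fit_iv_conductance(iv)
    if (f$ci95[1] <= G_true * 1000 && G_true * 1000 <= f$ci95[2])
      hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("applied-field conductance follows N z e / (t V)", {
  ev <- data.frame(particle_id = 1:25, species = "Na", valence = 1L,
                   t_cross = seq_len(25) * 4 - 2, direction = 1)
  g <- applied_field_conductance(ev, V = 200, duration = 100)
  expect_equal(g$G_pS, 200.2720793, tolerance = 1e-7)
  expect_true(g$sign_consistent)
  ## divalent with identical counts: exactly twice the conductance
  ev_ca <- transform(ev, species = "Ca", valence = 2L)
  g2 <- applied_field_conductance(ev_ca, V = 200, duration = 100)
  expect_equal(g2$G_pS / g$G_pS, 2)
  ## zero events -> zero conductance rows absent; V = 0 -> error
  expect_identical(nrow(applied_field_conductance(ev[0, ], 200, 100)), 0L)
  expect_error(applied_field_conductance(ev, V = 0, duration = 100),
               "fit_iv_conductance")
  ## counter-field flux flagged
  gneg <- applied_field_conductance(ev, V = -200, duration = 100)
  expect_false(gneg$sign_consistent)
})

test_that("selectivity ratios and Wilson intervals behave", {
  mk <- function(n_na, n_cl) {
    rbind(
      if (n_na) data.frame(particle_id = seq_len(n_na), species = "Na",
                           valence = 1L, t_cross = seq_len(n_na),
                           direction = 1) else NULL,
      if (n_cl) data.frame(particle_id = 100 + seq_len(n_cl),
                           species = "Cl", valence = -1L,
                           t_cross = seq_len(n_cl), direction = -1) else NULL)
  }
  s <- selectivity_ratio(mk(20, 2), "Na", "Cl")
  expect_equal(s$ratio, 10)
  expect_true(s$ratio_ci[1] < 10 && 10 < s$ratio_ci[2])
  expect_equal(selectivity_ratio(mk(5, 5), "Na", "Cl")$ratio, 1)
  ## no anion events: infinite ratio, one-sided interval
  sinf <- selectivity_ratio(mk(10, 0), "Na", "Cl")
  expect_identical(sinf$ratio, Inf)
  expect_identical(sinf$ratio_ci[2], Inf)
  expect_true(is.finite(sinf$ratio_ci[1]))
  ## equal Ca2+ and Na+ event counts: 1:1 permeation, 2:1 charge current
  ev <- rbind(data.frame(particle_id = 1:12, species = "Ca", valence = 2L,
                         t_cross = 1:12, direction = 1),
              data.frame(particle_id = 21:32, species = "Na", valence = 1L,
                         t_cross = 1:12, direction = 1))
  m <- selectivity_ratio(ev, "Ca", "Na")
  expect_equal(m$ratio, 1)
  expect_equal(m$charge_ratio, 2)
})

test_that("potential profiles integrate the 1D Poisson equation", {
  z <- seq(0, 10, length.out = 2001)
  ## zero charge -> zero potential
  p0 <- potential_profile_from_charge(z, rep(0, length(z)))
  expect_true(all(p0$phi_mV == 0))
  ## parallel-plate capacitor: slabs +/-rho0 of width w at 3 and 7 nm
  rho0 <- 0.05; w <- 0.5
  rho <- rho0 * (abs(z - 3) < w / 2) - rho0 * (abs(z - 7) < w / 2)
  pp <- potential_profile_from_charge(z, rho, force_zero = FALSE)
  cst <- channel_constants()
  ## surface charge of the discretized slab (trapezoid, matching the
  ## integrator's quadrature of the sharp edges)
  h <- z[2] - z[1]
  rhoL <- pmax(rho, 0)
  sigma_e <- sum((rhoL[-1] + rhoL[-length(rhoL)]) / 2 * h)
  sigma <- sigma_e * cst$e_charge * 1e27 * 1e-9         # C/m^2
  E_ref <- sigma / cst$eps0                             # V/m
  ## field between the plates: slope of phi in the gap, in V/m
  gap <- z > 4 & z < 6
  slope <- -coef(lm(pp$phi_mV[gap] / 1000 ~ z[gap]))[2] / 1e-9
  expect_equal(unname(slope), E_ref, tolerance = 1e-6)
  ## plateaus outside the plates
  left <- z < 2; right <- z > 8
  expect_lt(diff(range(pp$phi_mV[left])), 1e-9)
  expect_lt(diff(range(pp$phi_mV[right])), 1e-9)
  ## net-zero constraint pins both ends to zero
  pz <- potential_profile_from_charge(z, rho, force_zero = TRUE)
  expect_lt(abs(pz$phi_mV[1]), 1e-6)
  expect_lt(abs(pz$phi_mV[length(z)]), 1e-6)
  ## antisymmetric charge -> antisymmetric potential (the zero-difference
  ## boundary conditions single out the odd solution)
  rho_a <- 0.02 * sin(2 * pi * (z - 5) / 10)
  pa <- potential_profile_from_charge(z, rho_a, force_zero = TRUE)
  expect_lt(max(abs(pa$phi_mV + rev(pa$phi_mV))),
            1e-9 * max(abs(pa$phi_mV)))
  ## non-neutral input rejected
  expect_error(potential_profile_from_charge(z, rho + 0.01),
               "neutrality")
})

test_that("double integration inverts to the charge density at O(h^2)", {
  z <- seq(0, 10, length.out = 1001)
  h <- z[2] - z[1]
  rho <- 0.05 * sin(2 * pi * z / 10) + 0.02 * sin(4 * pi * z / 10)
  pp <- potential_profile_from_charge(z, rho, force_zero = FALSE)
  cst <- channel_constants()
  phi_V <- pp$phi_mV / 1000
  d2 <- diff(diff(phi_V)) / (h * 1e-9)^2
  rho_back <- -d2 * cst$eps0 / (cst$e_charge * 1e27)
  err <- max(abs(rho_back - rho[2:(length(z) - 1)]))
  expect_lt(err, 5 * max(abs(rho)) * (2 * pi * h / 10)^2)
})
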