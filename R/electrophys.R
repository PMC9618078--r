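## pA carried by one elementary charge per ns: e [C] / 1e-9 s -> A -> pA
.PA_PER_E_PER_NS <- 1.602176634e-19 / 1e-9 * 1e12  # = 160.2176634

#' Windowed ionic current from permeation events
#'
#' Ionic current within overlapping time windows (defaults 20 ns windows
#' with 10 ns overlap): `I_w = sum(direction * valence) * e / window`,
#' converted to pA. Event counting (transition counting) rather than
#' instantaneous charge flux keeps the estimate noise-free at small counts.
#'
#' @param tally an `event_tally` from [tally_events()] (or a plain events
#'   data.frame)
#' @param window window length, ns
#' @param overlap overlap between consecutive windows, ns (< window)
#' @param t_range analysis span c(t0, t1); defaults to the tally's range
#' @return data.frame of class `current_series`: window center (ns),
#'   current (pA) and per-species currents
#' @export
windowed_current <- function(tally, window = 20, overlap = 10,
                             t_range = NULL) {
  if (inherits(tally, "event_tally")) {
    events <- tally$events
    if (is.null(t_range)) t_range <- tally$t_range
  } else {
    events <- as.data.frame(tally)
    if (is.null(t_range))
      t_range <- c(0, if (nrow(events)) max(events$t_cross) else window)
  }
  if (window <= overlap || overlap < 0)
    stop("need window > overlap >= 0")
  span <- t_range[2] - t_range[1]
  if (window > span) {
    warning("window longer than trajectory; falling back to a single window")
    window <- span
    starts <- t_range[1]
  } else {
    stride <- window - overlap
    starts <- seq(t_range[1], t_range[2] - window, by = stride)
  }
  sp <- sort(unique(as.character(events$species)))
  rows <- lapply(starts, function(s0) {
    inw <- events$t_cross >= s0 & events$t_cross < s0 + window
    qsum <- sum(events$direction[inw] * events$valence[inw])
    row <- data.frame(t_center = s0 + window / 2,
                      current_pA = qsum * .PA_PER_E_PER_NS / window)
    for (s in sp) {
      iw <- inw & events$species == s
      row[[paste0("I_", s, "_pA")]] <-
        sum(events$direction[iw] * events$valence[iw]) *
        .PA_PER_E_PER_NS / window
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "window_ns") <- window
  attr(out, "overlap_ns") <- overlap
  class(out) <- c("current_series", class(out))
  out
}

#' Fit single-channel conductance from a current-voltage dataset
#'
#' Ordinary least squares `I = G V + b` on the chosen voltage subset, with
#' a 95% confidence interval on the slope from its standard error and the
#' Student-t quantile. The slope is reported in pS (pA/mV x 1000); the
#' intercept (reversal-potential offset) is reported but not folded into G.
#'
#' @param iv data.frame with columns `V_mV` and `I_pA`
#' @param subset `"full"` (all points), `"depolarized"` (V > 0) or
#'   `"polarized"` (V < 0)
#' @param force_zero_intercept fit through the origin instead
#' @return object of class `conductance_fit`: `G_pS`, `ci95`,
#'   `intercept_pA`, `subset`, `n`, and the underlying `lm` fit
#' @export
fit_iv_conductance <- function(iv, subset = c("full", "depolarized",
                                              "polarized"),
                               force_zero_intercept = FALSE) {
  subset <- match.arg(subset)
  iv <- as.data.frame(iv)
  stopifnot(all(c("V_mV", "I_pA") %in% names(iv)))
  d <- switch(subset,
              full = iv,
              depolarized = iv[iv$V_mV > 0, , drop = FALSE],
              polarized = iv[iv$V_mV < 0, , drop = FALSE])
  if (length(unique(d$V_mV)) < 2L)
    stop("fit error: need at least 2 distinct voltages in subset '",
         subset, "'")
  fit <- if (force_zero_intercept) stats::lm(I_pA ~ V_mV - 1, data = d)
         else stats::lm(I_pA ~ V_mV, data = d)
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  if (!is.finite(co["V_mV", "Estimate"]))
    stop("fit error: singular design")
  G <- co["V_mV", "Estimate"] * 1000        # pA/mV -> pS
  se <- co["V_mV", "Std. Error"] * 1000
  df <- fit$df.residual
  half <- if (df > 0 && is.finite(se)) stats::qt(0.975, df) * se else 0
  if (!is.finite(half)) half <- 0
  b <- if (force_zero_intercept) 0 else co["(Intercept)", "Estimate"]
  structure(list(G_pS = G, ci95 = c(G - half, G + half), se_pS = se,
                 intercept_pA = b, subset = subset, n = nrow(d), fit = fit),
            class = "conductance_fit")
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat(sprintf("G_%s = %.1f pS (95%% CI %.1f to %.1f, n = %d, intercept %.2f pA)\n",
              x$subset, x$G_pS, x$ci95[1], x$ci95[2], x$n, x$intercept_pA))
  invisible(x)
}

#' Conductance from an applied-field run
#'
#' For a single-bilayer run at fixed applied potential, the per-species
#' conductance is the permeation count times the valence magnitude times e,
#' divided by duration and potential:
#' `G_s = N_s |z_s| e / (duration |V|)`, in pS. `N_s` is the magnitude of
#' the net signed event count; the sign of the implied current is checked
#' against the sign of V and reported.
#'
#' @param events data.frame from [detect_permeation_events()]
#' @param V applied potential, mV (nonzero)
#' @param duration simulated time, ns
#' @return data.frame per species: n_events (net), G_pS, sign_consistent
#' @export
applied_field_conductance <- function(events, V, duration) {
  if (V == 0)
    stop("division error: V = 0; use fit_iv_conductance on an I-V dataset")
  if (duration <= 0) stop("duration must be > 0")
  events <- as.data.frame(events)
  sp <- sort(unique(as.character(events$species)))
  if (!length(sp))
    return(data.frame(species = character(), n_events = numeric(),
                      G_pS = numeric(), sign_consistent = logical()))
  do.call(rbind, lapply(sp, function(s) {
    es <- events[events$species == s, ]
    net <- sum(es$direction)
    q <- abs(es$valence[1])
    ## net charge motion (direction * valence summed) vs driving sign:
    ## positive V drives cations outer->inner (positive direction)
    i_sign <- sign(sum(es$direction * es$valence))
    G <- abs(net) * q * .E_CHARGE / (duration * 1e-9 * abs(V) * 1e-3) * 1e12
    data.frame(species = s, n_events = net, G_pS = G,
               sign_consistent = (i_sign == 0) | (i_sign == sign(V)))
  }))
}

#' Cation/anion selectivity from event counts
#'
#' Ratio of cation to anion permeation event counts with a Wilson score
#' interval on the cation fraction (propagated to the ratio). Also reports
#' the charge-current ratio, which weights events by valence.
#'
#' @param tally an `event_tally` (or events data.frame)
#' @param cation_species labels counted as cations
#' @param anion_species labels counted as anions
#' @param conf confidence level for the Wilson interval
#' @return list: `ratio`, `ratio_ci`, `n_cation`, `n_anion`,
#'   `charge_ratio`, `cation_fraction`, `fraction_ci`
#' @export
selectivity_ratio <- function(tally, cation_species, anion_species,
                              conf = 0.95) {
  events <- if (inherits(tally, "event_tally")) tally$events
            else as.data.frame(tally)
  if (nrow(events) == 0L) stop("need at least one event")
  ic <- events$species %in% cation_species
  ia <- events$species %in% anion_species
  n_c <- sum(abs(events$direction[ic]))
  n_a <- sum(abs(events$direction[ia]))
  q_c <- sum(abs(events$direction[ic] * events$valence[ic]))
  q_a <- sum(abs(events$direction[ia] * events$valence[ia]))
  n <- n_c + n_a
  if (n == 0L) stop("need at least one cation or anion event")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- n_c / n
  wilson <- (p + z^2 / (2 * n) +
               c(-1, 1) * z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  wilson <- pmin(pmax(wilson, 0), 1)
  ratio <- if (n_a == 0) Inf else n_c / n_a
  ratio_ci <- wilson / (1 - wilson)
  if (n_a == 0) ratio_ci[2] <- Inf
  list(ratio = ratio, ratio_ci = ratio_ci, n_cation = n_c, n_anion = n_a,
       charge_ratio = if (q_a == 0) Inf else q_c / q_a,
       cation_fraction = p, fraction_ci = wilson)
}

#' Transmembrane potential profile from a charge-density profile
#'
#' Double integration of the 1D Poisson equation
#' `phi(z) = -(1/eps0 epsr) int int rho`, evaluated by cumulative
#' trapezoids. With `force_zero = TRUE` (default) a linear ramp is
#' subtracted so the net potential difference across the box is zero and
#' both ends sit at 0 mV; the grid is recentered so z = 0 lies at the box
#' center. Charge neutrality of the input profile is enforced.
#'
#' @param z grid, nm (uniform)
#' @param rho charge density, e/nm^3
#' @param eps_r relative permittivity (default 1: all charges explicit)
#' @param force_zero subtract the ramp enforcing zero net potential
#'   difference
#' @param net_tol neutrality tolerance on |int rho dz|, e/nm^2
#' @return object of class `potential_profile`: `z` (recentered, nm),
#'   `phi_mV`, `dphi_mV` (difference across the box before any ramp)
#' @export
potential_profile_from_charge <- function(z, rho, eps_r = 1,
                                          force_zero = TRUE,
                                          net_tol = 1e-6) {
  stopifnot(length(z) == length(rho), length(z) >= 3)
  h <- diff(z)
  if (max(abs(h - h[1])) > 1e-9 * abs(h[1]))
    stop("z grid must be uniform")
  cumtrapz <- function(y) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * h))
  net <- sum((rho[-1] + rho[-length(rho)]) / 2 * h)
  if (abs(net) > net_tol)
    stop(sprintf("neutrality error: net charge %.3g e/nm^2 exceeds tolerance",
                 net))
  ## E(z) = (1/eps0 epsr) int rho dz'; phi = -int E dz
  ## units: rho e/nm^3 -> C/m^3 (x e x 1e27); z nm -> m (x 1e-9)
  rho_SI <- rho * .E_CHARGE * 1e27
  E <- cumtrapz(rho_SI) * 1e-9 / (.EPS0 * eps_r)     # V/m
  phi <- -cumtrapz(E) * 1e-9                          # V
  dphi <- phi[length(phi)] - phi[1]
  if (force_zero)
    phi <- phi - dphi * (z - z[1]) / (z[length(z)] - z[1])
  phi <- phi - phi[1]
  structure(list(z = z - mean(range(z)), phi_mV = phi * 1000,
                 dphi_mV = dphi * 1000, eps_r = eps_r,
                 force_zero = force_zero),
            class = "potential_profile")
}

#' Stationary Smoluchowski current through a 1D channel
#'
#' Analytic (quadrature) steady-state solution of the 1D drift-diffusion
#' equation on a periodic box for the same total potential the Langevin
#' generator integrates: PMF plus a linear applied-potential drop across
#' the channel span. The nonconservative loop work per period sustains a
#' stationary flux (Stratonovich tilted-periodic-potential formula),
#' providing an independent reference for the event-counting conductance
#' pipeline.
#'
#' @param spec a [channel_sim_spec()] (must be periodic)
#' @param T temperature, K
#' @param n_grid quadrature grid size
#' @return data.frame per species: flux (particles/ns, + = outer-to-inner),
#'   current_pA, G_pS (current over |V|; NA at V = 0)
#' @export
smoluchowski_current <- function(spec, T = 300, n_grid = 8192) {
  stopifnot(inherits(spec, "channel_sim_spec"))
  kT <- kt_kcal(T)
  L <- spec$box[3]
  z <- seq(0, L, length.out = n_grid)
  h <- z[2] - z[1]
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * h
  cumtrap <- function(y) c(0, cumsum((y[-1] + y[-length(y)]) / 2) * h)
  out <- lapply(names(spec$n_ions), function(s) {
    q <- spec$valence[s]; D <- spec$diffusion[s]; N <- spec$n_ions[s]
    psi <- .u_total(z, spec, q) / kT
    psi <- psi - mean(psi)                 # numeric conditioning
    Delta <- (.u_total(L, spec, q) - .u_total(0, spec, q)) / kT
    ep <- exp(psi); em <- exp(-psi)
    A <- trap(ep)
    B <- cumtrap(ep)
    I1 <- trap(em)
    I2 <- trap(em * B)
    C <- N / (I1 - (1 - exp(Delta)) * I2 / A)
    J_up <- D * C * (1 - exp(Delta)) / A   # particles/ns in +z
    flux_in <- -J_up                        # outer-to-inner positive
    I_pA <- q * flux_in * .PA_PER_E_PER_NS
    data.frame(species = s, flux_per_ns = flux_in, current_pA = I_pA,
               G_pS = if (spec$voltage != 0)
                 I_pA / spec$voltage * 1000 else NA_real_)
  })
  do.call(rbind, out)
}
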