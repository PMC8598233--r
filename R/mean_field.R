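# Mean-field effective description of the PBM: occupancy, effective
# diffusivity/potential, the concentration-diffusivity scaling relation, and
# the predicted radial drift used to reject the PBM on tracking data.

#' Probability of being unbound at local site density rho
#'
#' `pu = k_off / (k_off + k_plus * rho)`. With `k_off = 0` and `rho > 0` the
#' tracer is fully bound and 0 is returned.
#'
#' @param rho_r Local binding-site density (um^-3), >= 0.
#' @param k_plus On-rate constant (um^3/s).
#' @param k_off Unbinding rate (s^-1).
#' @return Probability in (0, 1] (0 in the fully bound limit).
#' @export
p_unbound <- function(rho_r, k_plus, k_off) {
  if (any(rho_r < 0) || any(k_plus < 0) || any(k_off < 0))
    stop("p_unbound requires non-negative arguments")
  ifelse(k_off == 0 & rho_r > 0, 0, k_off / (k_off + k_plus * rho_r))
}

#' Effective diffusivity of a transiently binding tracer
#'
#' Occupancy-weighted average `pu * Dn + (1 - pu) * Db` between free and
#' bound motion.
#'
#' @param pu Probability of being unbound, in \[0, 1\].
#' @param Dn Free diffusivity (um^2/s).
#' @param Db Bound (site) diffusivity (um^2/s).
#' @return Effective diffusivity (um^2/s).
#' @export
effective_diffusivity <- function(pu, Dn, Db) {
  if (any(pu < 0 | pu > 1)) stop("pu must lie in [0, 1]")
  pu * Dn + (1 - pu) * Db
}

#' Effective potential implied by the effective diffusivity
#'
#' `U_eff = ln((D_eff - Db) / (Dn - Db))` in kBT (<= 0): the fingerprint
#' relation of the binding-site picture. Consistency:
#' `exp(-U_eff) = 1 + k_plus rho / k_off = 1/pu`, so the Boltzmann density
#' built from `U_eff` reproduces the occupancy-based density.
#'
#' @param D_eff Effective diffusivity (um^2/s), `Db < D_eff <= Dn`.
#' @param Dn Free diffusivity (um^2/s).
#' @param Db Bound diffusivity (um^2/s).
#' @return Potential in kBT.
#' @export
effective_potential <- function(D_eff, Dn, Db) {
  if (any(D_eff <= Db))
    stop("D_eff <= Db: bound-dominated regime, the effective description fails")
  if (any(D_eff > Dn + 1e-12)) stop("D_eff must not exceed Dn")
  log((D_eff - Db) / (Dn - Db))
}

#' Concentration-diffusivity scaling test of the PBM
#'
#' The binding-site picture enforces `p(r) propto 1 / (D_eff(r) - Db)`, i.e.
#' for plateau values `(D0 - Db) / (Dn - Db) = pout / pin`. The relative
#' deviation between the two sides measures departure from the binding-site
#' model; PBM-generated data fall on the identity within statistical error,
#' while a droplet with independently chosen `(D0, A)` can violate it
#' strongly.
#'
#' @param pin,pout Plateau densities inside/outside the focus (`pin > pout > 0`).
#' @param D0_meas,Dn_meas Measured diffusivity plateaus inside/outside
#'   (`Dn_meas > D0_meas > Db`).
#' @param Db Assumed binding-site diffusivity (um^2/s).
#' @return List with `x = (D0 - Db)/(Dn - Db)`, `y = pout/pin`, the relative
#'   `deviation = |x - y| / y`, and `Db_star`, the site diffusivity that
#'   would force equality.
#' @export
scaling_test <- function(pin, pout, D0_meas, Dn_meas, Db) {
  if (!(pin > pout && pout > 0)) stop("scaling_test requires pin > pout > 0")
  if (!(Dn_meas > D0_meas && D0_meas > Db))
    stop("scaling_test requires Dn_meas > D0_meas > Db")
  x <- (D0_meas - Db) / (Dn_meas - Db)
  y <- pout / pin
  list(x = x, y = y, deviation = abs(x - y) / y,
       Db_star = (D0_meas - y * Dn_meas) / (1 - y))
}

#' Predicted mean radial displacement from measured profiles
#'
#' Under spherical symmetry the binding-site picture predicts
#' `<dr>(r) = dt * (-D_eff dU_eff/dr + dD_eff/dr + (d - 1) D_eff / r)`,
#' where the effective potential is read off the measured density via
#' `U_eff = -ln p(r) + const` (Boltzmann-consistent sign). The
#' `(d - 1) D/r` term is the coordinate drift: `D/r` for 2D-projected
#' tracks (`d = 2`, the default for observed data), `2 D/r` for full 3D
#' trajectories.
#'
#' @param profile A list or data.frame with numeric fields `r` (bin centres,
#'   um), `D` (effective diffusivity per bin) and `p` (density per bin);
#'   optional `D_se` and `p_se` propagate to a prediction standard error.
#' @param dt_obs Observation interval (s).
#' @param d Observation dimension, 2 (projected tracks) or 3.
#' @return data.frame with `r`, `drift` (um) and `se` (NA when no bin
#'   uncertainties were supplied; endpoints use one-sided differences).
#'
#' @details Numerically the drift is evaluated in the equivalent conservative
#' (flux) form `dt * d/dr(r^{d-1} D p) / (r^{d-1} p)`, differencing the
#' product `r^{d-1} D p` rather than `D` and `ln p` separately: across the
#' focus boundary the density rise and the diffusivity drop nearly cancel in
#' the product (the scaling relation), so this discretization stays accurate
#' where term-by-term finite differences of the steep individual profiles
#' ring badly.
#' @export
predicted_radial_drift <- function(profile, dt_obs, d = 2) {
  r <- profile$r
  D <- profile$D
  p <- profile$p
  if (!(d %in% c(2, 3))) stop("d must be 2 or 3")
  if (any(!is.finite(p)) || any(p <= 0))
    stop("non-positive or missing density bins; restrict the profile first")
  if (any(!is.finite(D))) stop("missing diffusivity bins")
  n <- length(r)
  if (n < 3) stop("need at least 3 bins")
  w <- r^(d - 1)
  q <- w * D * p
  cd <- function(v) {  # central differences, one-sided at the ends
    dv <- numeric(n)
    dv[1] <- (v[2] - v[1]) / (r[2] - r[1])
    dv[n] <- (v[n] - v[n - 1]) / (r[n] - r[n - 1])
    if (n > 2) dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (r[3:n] - r[1:(n - 2)])
    dv
  }
  drift <- dt_obs * cd(q) / (w * p)
  se <- rep(NA_real_, n)
  if (!is.null(profile$D_se) || !is.null(profile$p_se)) {
    # delta-method propagation, bins treated as independent
    D_se <- if (is.null(profile$D_se)) rep(0, n) else profile$D_se
    p_se <- if (is.null(profile$p_se)) rep(0, n) else profile$p_se
    q_se <- w * sqrt((D * p_se)^2 + (p * D_se)^2)
    dq_se <- numeric(n)
    dq_se[1] <- sqrt(q_se[1]^2 + q_se[2]^2) / (r[2] - r[1])
    dq_se[n] <- sqrt(q_se[n - 1]^2 + q_se[n]^2) / (r[n] - r[n - 1])
    if (n > 2) dq_se[2:(n - 1)] <- sqrt(q_se[3:n]^2 + q_se[1:(n - 2)]^2) /
        (r[3:n] - r[1:(n - 2)])
    se <- dt_obs * dq_se / (w * p)
  }
  data.frame(r = r, drift = drift, se = se)
}

#' Equilibrium radial density of the PBM
#'
#' `p(r) propto 1 + rho(r)/Kd` with `Kd = k_off / k_plus` and a sharp site
#' density `rho(r) = rho` for `r < r_f`, 0 outside, normalized so that
#' `integral 4 pi r^2 p(r) dr = 1` over the nucleus. The plateau ratio is
#' `pin/pout = 1 + k_plus rho / k_off`.
#'
#' @param p A [pbm_params()].
#' @param r_grid Radii (um) at which to evaluate the density.
#' @return Numeric vector of densities (um^-3).
#' @export
equilibrium_density_pbm <- function(p, r_grid) {
  stopifnot(inherits(p, "pbm_params"))
  g <- p$geometry
  k_plus <- smoluchowski_k_plus(p$Dn, p$r_b, p$kappa)
  enh <- 1 + k_plus * p$rho / p$k_off
  v_f <- 4 / 3 * pi * g$r_f^3
  v_n <- 4 / 3 * pi * g$r_n^3
  z <- v_n + (enh - 1) * v_f
  ifelse(r_grid < g$r_f, enh, 1) / z
}

#' Microscopic equilibrium enhancement of the simulated binding-site model
#'
#' The event-resolved simulator resolves rebinding explicitly, so its true
#' equilibrium in/out density ratio follows from surface-exchange detailed
#' balance: `pin/pout = 1 + 4 pi r_b^2 kappa rho / k_off`. This equals the
#' Smoluchowski-based mean-field ratio `1 + k_plus rho / k_off`
#' ([equilibrium_density_pbm()]) multiplied by `1 + kappa r_b / Dn`: the two
#' coincide in the reaction-limited regime `kappa r_b / Dn << 1`, and the
#' factor is exactly the rebinding renormalization of the unbinding rate.
#'
#' @param p A [pbm_params()].
#' @param renormalized If `FALSE`, return the Smoluchowski mean-field ratio
#'   instead.
#' @return The equilibrium density ratio inside/outside the focus.
#' @export
pbm_equilibrium_enhancement <- function(p, renormalized = TRUE) {
  stopifnot(inherits(p, "pbm_params"))
  if (renormalized) 1 + 4 * pi * p$r_b^2 * p$kappa * p$rho / p$k_off
  else 1 + smoluchowski_k_plus(p$Dn, p$r_b, p$kappa) * p$rho / p$k_off
}
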