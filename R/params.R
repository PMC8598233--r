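#' @useDynLib focisim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd integrate ks.test chisq.test optimize approx
#' @importFrom utils head tail
NULL

# Unit conventions used throughout: lengths um, times s, diffusivities um^2/s,
# energies in units of kBT (kBT = 1 internally), number densities um^-3,
# rates s^-1.

#' Concentric focus/nucleus geometry
#'
#' The focus and the nucleus are concentric spheres centred at the origin.
#'
#' @param r_f Focus radius (um), 0 < `r_f` < `r_n`.
#' @param r_n Nucleus radius (um).
#' @return An object of class `"geometry"`.
#' @export
geometry <- function(r_f = 0.1, r_n = 0.5) {
  stopifnot(is.finite(r_f), is.finite(r_n))
  if (!(r_f > 0 && r_f < r_n)) stop("geometry requires 0 < r_f < r_n")
  structure(list(r_f = r_f, r_n = r_n), class = "geometry")
}

#' Liquid Phase Model parameters
#'
#' The droplet is described by sigmoidal radial profiles for the diffusivity
#' and the potential: `D(r) = D0 + (Dn - D0)/(1 + exp(-b (r - r_f)))` and
#' `U(r) = A/(1 + exp(-b (r - r_f)))`. The potential is low *inside* the
#' focus, so the equilibrium density ratio inside/outside equals `exp(A)` for
#' attractive foci (A >= 0).
#'
#' Defaults are the typical values used throughout: `D0 = 0.05`, `Dn = 1.0`
#' um^2/s, `A = 5` kBT, `b = 1000` um^-1.
#'
#' @param geom A [geometry()].
#' @param D0 Diffusivity inside the focus (um^2/s), 0 < D0 <= Dn.
#' @param Dn Diffusivity in the nucleoplasm (um^2/s).
#' @param A Potential step in kBT; A >= 0 means an attractive focus.
#' @param b Boundary steepness (um^-1), > 0.
#' @return An object of class `"lpm_params"`.
#' @export
lpm_params <- function(geom = geometry(), D0 = 0.05, Dn = 1.0, A = 5.0,
                       b = 1000) {
  stopifnot(inherits(geom, "geometry"), is.finite(D0), is.finite(Dn),
            is.finite(A), is.finite(b))
  if (!(D0 > 0 && D0 <= Dn)) stop("lpm_params requires 0 < D0 <= Dn")
  if (b <= 0) stop("lpm_params requires b > 0")
  structure(list(geometry = geom, D0 = D0, Dn = Dn, A = A, b = b),
            class = "lpm_params")
}

#' Polymer Bridging Model parameters
#'
#' The focus is a cluster of `N = round((4/3) pi rho r_f^3)` spherical,
#' partially absorbing binding sites of radius `r_b`, confined to the focus
#' and diffusing with diffusivity `Db`. An unbound tracer diffuses at `Dn`
#' everywhere; on crossing a site surface it is absorbed with the per-step
#' probability given by [absorption_probability()], otherwise reflected.
#' Bound tracers ride their site and release at rate `k_off`.
#'
#' @param geom A [geometry()].
#' @param Dn Free-tracer diffusivity (um^2/s).
#' @param Db Binding-site diffusivity (um^2/s), >= 0.
#' @param rho Binding-site number density inside the focus (um^-3).
#' @param r_b Binding-site radius (um), < r_f.
#' @param kappa Absorption parameter of the Robin condition (um/s).
#' @param k_off Unbinding rate (s^-1).
#' @param crowder_count Number of inert (never-absorbing) spheres of radius
#'   `r_b` added to the focus; 0 disables crowding.
#' @return An object of class `"pbm_params"`.
#' @export
pbm_params <- function(geom = geometry(), Dn = 1.0, Db = 0.005, rho = 4.8e4,
                       r_b = 0.01, kappa = 100, k_off = 500,
                       crowder_count = 0L) {
  stopifnot(inherits(geom, "geometry"))
  if (Dn <= 0 || rho < 0 || r_b <= 0 || kappa < 0 || k_off <= 0)
    stop("pbm_params: Dn, r_b, k_off must be > 0; rho, kappa >= 0")
  if (Db < 0) stop("pbm_params requires Db >= 0")
  if (r_b >= geom$r_f) stop("pbm_params requires r_b < r_f")
  if (crowder_count < 0) stop("crowder_count must be >= 0")
  structure(list(geometry = geom, Dn = Dn, Db = Db, rho = rho, r_b = r_b,
                 kappa = kappa, k_off = k_off,
                 crowder_count = as.integer(crowder_count)),
            class = "pbm_params")
}

#' Number of binding sites implied by a density
#' @param p A [pbm_params()].
#' @return Integer `N = round((4/3) pi rho r_f^3)`.
#' @export
n_binding_sites <- function(p) {
  stopifnot(inherits(p, "pbm_params"))
  as.integer(round(4 / 3 * pi * p$rho * p$geometry$r_f^3))
}

#' Simulation configuration
#'
#' `dt` is the integration step; output is thinned by `record_every` so the
#' recorded spacing is `dt * record_every`. The same seed always yields the
#' identical trajectory.
#'
#' @param dt Integration step (s), > 0.
#' @param n_steps Number of integration steps.
#' @param seed Integer seed controlling all randomness of the run.
#' @param record_every Thinning factor for output frames.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt = 1e-6, n_steps = 1e6, seed = 1L,
                       record_every = 1L) {
  if (!(dt > 0)) stop("dt must be > 0")
  n_steps <- round(n_steps)
  record_every <- as.integer(record_every)
  if (n_steps < 1 || record_every < 1) stop("n_steps and record_every must be >= 1")
  structure(list(dt = dt, n_steps = n_steps, seed = as.integer(seed),
                 record_every = record_every),
            class = "sim_config")
}

# PBM stability checks: per-step absorption probability well below 1 and free
# step length << site radius. Above pb ~ 0.2 the pb <-> kappa mapping of
# absorption_probability() acquires O(pb) corrections (the scheme stays
# internally consistent at an effective absorptivity), so the hard error only
# triggers at 0.35.
check_pbm_stability <- function(p, cfg, pb_max = 0.35, step_frac = 0.25) {
  pb <- absorption_probability(p$kappa, cfg$dt, p$Dn)
  if (pb > pb_max)
    stop(sprintf("unstable configuration: per-step absorption probability %.3g > %.2g; decrease dt (see pbm_stable_dt)", pb, pb_max))
  if (sqrt(2 * p$Dn * cfg$dt) > step_frac * p$r_b)
    stop(sprintf("unstable configuration: step length %.3g um is not << r_b = %.3g um; decrease dt", sqrt(2 * p$Dn * cfg$dt), p$r_b))
  if (p$k_off * cfg$dt > 0.5)
    stop("k_off * dt exceeds 0.5; decrease dt")
  invisible(pb)
}

#' Largest stable integration step for a PBM configuration
#'
#' Returns the largest `dt` satisfying the discretization conditions
#' (per-step absorption probability below `pb_max`, free step length below
#' `step_frac * r_b`, and `k_off * dt <= 0.25`).
#'
#' @param p A [pbm_params()].
#' @param pb_max Upper bound on the per-step absorption probability.
#' @param step_frac Upper bound on step length as a fraction of `r_b`.
#' @return A time step in seconds.
#' @export
pbm_stable_dt <- function(p, pb_max = 0.1, step_frac = 0.15) {
  stopifnot(inherits(p, "pbm_params"))
  dt1 <- if (p$kappa > 0) (pb_max / p$kappa)^2 * p$Dn / pi else Inf
  dt2 <- (step_frac * p$r_b)^2 / (2 * p$Dn)
  dt3 <- 0.25 / p$k_off
  min(dt1, dt2, dt3)
}

#' Droplet diffusivity profile
#'
#' `D(r) = D0 + (Dn - D0) / (1 + exp(-b (r - r_f)))`: equals `D0` deep inside
#' the focus, `Dn` far outside, and the midpoint `(D0 + Dn)/2` at `r = r_f`.
#'
#' @param r Radial distance(s) from the focus centre (um), >= 0.
#' @param p An [lpm_params()].
#' @return Diffusivity in um^2/s, vectorized over `r`.
#' @export
lpm_diffusivity <- function(r, p) {
  stopifnot(inherits(p, "lpm_params"))
  if (any(r < 0)) stop("r must be >= 0")
  p$D0 + (p$Dn - p$D0) * plogis(p$b * (r - p$geometry$r_f))
}

#' Droplet potential profile
#'
#' `U(r) = A / (1 + exp(-b (r - r_f)))` in kBT: approximately 0 inside the
#' focus and A outside, so an attractive focus (A > 0) holds an equilibrium
#' density ratio inside/outside of `exp(A)`.
#'
#' @inheritParams lpm_diffusivity
#' @return Potential in kBT, vectorized over `r`.
#' @export
lpm_potential <- function(r, p) {
  stopifnot(inherits(p, "lpm_params"))
  if (any(r < 0)) stop("r must be >= 0")
  p$A * plogis(p$b * (r - p$geometry$r_f))
}

#' Smoluchowski rate constant for a partially absorbing sphere
#'
#' `k+ = 4 pi Dn r_b / (1 + Dn / (r_b kappa))` (um^3/s), the diffusion-limited
#' on-rate to a sphere of radius `r_b` with Robin absorption parameter
#' `kappa`; `kappa = Inf` gives the fully absorbing limit `4 pi Dn r_b`.
#'
#' @param Dn Tracer diffusivity (um^2/s), > 0.
#' @param r_b Site radius (um), > 0.
#' @param kappa Absorption parameter (um/s), > 0 (`Inf` allowed).
#' @return Rate constant in um^3/s.
#' @export
smoluchowski_k_plus <- function(Dn, r_b, kappa) {
  if (any(Dn <= 0) || any(r_b <= 0) || any(kappa <= 0))
    stop("smoluchowski_k_plus requires strictly positive arguments")
  4 * pi * Dn * r_b / (1 + ifelse(is.infinite(kappa), 0, Dn / (r_b * kappa)))
}

#' Per-step absorption probability at a site surface
#'
#' The discretized Robin boundary condition `Dn dp/dn = kappa p` yields a
#' per-step absorption probability `pb = kappa * sqrt(pi * dt / Dn)` for a
#' tracer that crosses the site surface during a step of length `dt`. This is
#' the standard dimensionally consistent form for a partially absorbing
#' boundary (`kappa` has units um/s); it scales as `sqrt(dt)` and is
#' invariant under the rescaling length -> lambda * length,
#' time -> lambda^2 * time.
#'
#' @param kappa Absorption parameter (um/s), >= 0.
#' @param dt Time step (s).
#' @param Dn Tracer diffusivity (um^2/s).
#' @return A probability; an error is raised if it reaches 1.
#' @export
absorption_probability <- function(kappa, dt, Dn) {
  if (any(kappa < 0) || any(dt <= 0) || any(Dn <= 0))
    stop("absorption_probability requires kappa >= 0, dt > 0, Dn > 0")
  pb <- kappa * sqrt(pi * dt / Dn)
  if (any(pb >= 1))
    stop("absorption probability >= 1: dt too large for this kappa")
  pb
}

#' Unbinding rate implied by a molar dissociation constant
#'
#' Converts `Kd` (mol/L) to a number density (um^-3) via Avogadro's number
#' and 1 L = 1e15 um^3, then returns `k_off = Kd * k_plus`.
#'
#' @param kd_molar Dissociation constant in mol/L.
#' @param k_plus On-rate constant in um^3/s (e.g. [smoluchowski_k_plus()]).
#' @return Unbinding rate in s^-1.
#' @export
koff_from_kd <- function(kd_molar, k_plus) {
  if (any(kd_molar <= 0) || any(k_plus <= 0))
    stop("koff_from_kd requires positive arguments")
  kd_per_um3 <- kd_molar * 6.02214076e23 / 1e15
  kd_per_um3 * k_plus
}

#' @importFrom stats plogis
NULL

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("focus/nucleus geometry: r_f = %g um, r_n = %g um\n", x$r_f, x$r_n))
  invisible(x)
}

#' @export
print.lpm_params <- function(x, ...) {
  cat(sprintf("LPM parameters: D0 = %g, Dn = %g um^2/s, A = %g kBT, b = %g um^-1; r_f = %g, r_n = %g um\n",
              x$D0, x$Dn, x$A, x$b, x$geometry$r_f, x$geometry$r_n))
  invisible(x)
}

#' @export
print.pbm_params <- function(x, ...) {
  cat(sprintf("PBM parameters: N = %d sites (rho = %g um^-3), r_b = %g um, Dn = %g, Db = %g um^2/s, kappa = %g um/s, k_off = %g s^-1; r_f = %g, r_n = %g um\n",
              n_binding_sites(x), x$rho, x$r_b, x$Dn, x$Db, x$kappa, x$k_off,
              x$geometry$r_f, x$geometry$r_n))
  if (x$crowder_count > 0) cat(sprintf("  + %d inert crowders\n", x$crowder_count))
  invisible(x)
}
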