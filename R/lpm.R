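# Langevin simulation of the droplet (LPM) model.

new_trajectory <- function(t, pos, bound = NULL, params = NULL, seed = NA_integer_,
                           dt = NA_real_, record_every = NA_integer_) {
  colnames(pos) <- c("x", "y", "z")
  structure(list(t = t, pos = pos, bound = bound, params = params,
                 seed = seed, dt = dt, record_every = record_every),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, spacing %g s, duration %g s%s\n",
              length(x$t), if (length(x$t) > 1) x$t[2] - x$t[1] else NA,
              max(x$t), if (!is.null(x$bound)) " (with bound flags)" else ""))
  invisible(x)
}

#' Simulate a tracer in the Liquid Phase Model
#'
#' Integrates the overdamped Langevin equation
#' `dr = dt [grad D - D grad U] + sqrt(2 D) dW` (Ito convention, kBT = 1)
#' with the sigmoidal droplet profiles of [lpm_diffusivity()] and
#' [lpm_potential()], a reflecting nucleus boundary at `r_n`, and the
#' Milstein multiplicative-noise correction applied along the radial
#' direction (D depends only on r). The spurious-drift term `grad D` is
#' essential for Boltzmann stationarity when `D0 != Dn`.
#'
#' @param p An [lpm_params()].
#' @param cfg A [sim_config()].
#' @param start Either a 3-vector (um) inside the nucleus, or
#'   `"equilibrium"` to draw the initial radius from the Boltzmann radial law
#'   (uniform angles).
#' @param milstein Use the Milstein correction (default). `FALSE` gives the
#'   plain Euler-Maruyama scheme, which needs a roughly 10x smaller `dt` for
#'   the same stationary accuracy.
#' @return A `"trajectory"` object with fields `t`, `pos` (n x 3, um),
#'   `params`, `seed`.
#' @export
simulate_lpm <- function(p, cfg, start = "equilibrium", milstein = TRUE) {
  stopifnot(inherits(p, "lpm_params"), inherits(cfg, "sim_config"))
  g <- p$geometry
  # warn (not fail) when the deterministic drift traverses the boundary layer
  # in a single step; the force peaks at r_f where D = (D0 + Dn)/2
  max_drift <- (p$D0 + p$Dn) / 2 * abs(p$A) * p$b / 4 * cfg$dt
  if (is.finite(max_drift) && max_drift > 1 / p$b)
    warning("drift * dt exceeds the boundary width 1/b; consider a smaller dt")
  start <- resolve_start_lpm(start, p, cfg$seed)
  if (sqrt(sum(start^2)) > g$r_n) stop("start position outside the nucleus")
  out <- cpp_simulate_lpm(start, g$r_f, g$r_n, p$D0, p$Dn, p$A, p$b,
                          cfg$dt, cfg$n_steps, cfg$record_every,
                          cfg$seed, milstein)
  new_trajectory(out$t, out$pos, bound = NULL, params = p, seed = cfg$seed,
                 dt = cfg$dt, record_every = cfg$record_every)
}

resolve_start_lpm <- function(start, p, seed) {
  if (is.character(start)) {
    if (!identical(start, "equilibrium"))
      stop("start must be a 3-vector or \"equilibrium\"")
    set.seed(seed)
    r <- sample_boltzmann_radius(p, 1)
    u <- random_unit_vector(1)
    return(as.numeric(r * u))
  }
  start <- as.numeric(start)
  if (length(start) != 3 || any(!is.finite(start)))
    stop("start must be a finite 3-vector")
  start
}

random_unit_vector <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# Rejection sampling of the Boltzmann radial law p(r) ~ r^2 exp(-U(r)) on
# [r_min, r_n]. Uses the current R RNG stream.
sample_boltzmann_radius <- function(p, n, r_min = 0) {
  g <- p$geometry
  rs <- numeric(0)
  # envelope: uniform radius, accept with exp(-(U - U_min))
  u_min <- min(lpm_potential(seq(r_min, g$r_n, length.out = 512), p))
  while (length(rs) < n) {
    m <- max(2L * (n - length(rs)), 64L)
    r <- (runif(m) * (g$r_n^3 - r_min^3) + r_min^3)^(1 / 3)  # uniform in shell volume
    acc <- runif(m) < exp(-(lpm_potential(r, p) - u_min))
    rs <- c(rs, r[acc])
  }
  rs[seq_len(n)]
}

#' Reflect a proposed position back into a sphere
#'
#' Radial mirror reflection at `|pos| = R`: positions inside are returned
#' unchanged; an outside proposal is mapped to `|result| = 2R - |pos_new|`
#' along the same direction, re-reflected if still outside. A proposal
#' beyond `3R` (step size grossly too large) is an error.
#'
#' @param pos_old Previous position (3-vector, um), must satisfy
#'   `|pos_old| <= R`.
#' @param pos_new Proposed position (3-vector, um).
#' @param R Sphere radius (um).
#' @return The reflected position.
#' @export
reflect_sphere <- function(pos_old, pos_new, R) {
  if (sqrt(sum(pos_old^2)) > R * (1 + 1e-12))
    stop("pos_old must lie inside the sphere")
  r <- sqrt(sum(pos_new^2))
  if (r > 3 * R) stop("proposed position beyond 3R: step far too large")
  guard <- 0
  while (r > R && guard < 64) {
    rnew <- abs(2 * R - r)
    pos_new <- pos_new * if (r > 0) rnew / r else 0
    r <- rnew
    guard <- guard + 1
  }
  pos_new
}

#' Boltzmann stationary radial density of the LPM
#'
#' Returns `p(r) = exp(-U(r)) / Z` with the normalization
#' `integral 4 pi r^2 p(r) dr = 1` over the nucleus, i.e. the density per
#' unit volume at radius `r`.
#'
#' @param p An [lpm_params()].
#' @param r_grid Radii (um) within `[0, r_n]`.
#' @return Numeric vector of densities (um^-3) matching `r_grid`.
#' @export
stationary_density_lpm <- function(p, r_grid) {
  stopifnot(inherits(p, "lpm_params"))
  if (length(r_grid) == 0) stop("empty radius grid")
  if (any(r_grid < 0 | r_grid > p$geometry$r_n))
    stop("r_grid must lie in [0, r_n]")
  z <- integrate(function(r) 4 * pi * r^2 * exp(-lpm_potential(r, p)),
                 0, p$geometry$r_n, rel.tol = 1e-10)$value
  exp(-lpm_potential(r_grid, p)) / z
}
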