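# Target-search theory: mean first-passage time to a perfectly absorbing
# target at the focus centre, the optimal focus size, and the generalized
# Berg-Purcell sensing limit.

#' Search problem specification
#'
#' Absorbing target sphere of radius `r0` at the centre of the focus, which
#' sits at the centre of a reflecting nucleus: `0 < r0 < r_f < r_n`.
#'
#' @param r0 Target radius (um).
#' @param geom A [geometry()].
#' @param D0,Dn Diffusivities inside/outside the focus (um^2/s).
#' @param A Potential step (kBT), attractive focus for A > 0.
#' @param b Boundary steepness (um^-1) for quadrature-mode profiles.
#' @return An object of class `"search_spec"`.
#' @export
search_spec <- function(r0, geom = geometry(), D0 = 0.05, Dn = 1.0, A = 5.0,
                        b = 1000) {
  if (!(r0 > 0 && r0 < geom$r_f)) stop("search_spec requires 0 < r0 < r_f")
  structure(list(r0 = r0, geometry = geom, D0 = D0, Dn = Dn, A = A, b = b),
            class = "search_spec")
}

as_lpm <- function(spec) lpm_params(spec$geometry, spec$D0, spec$Dn, spec$A, spec$b)

#' Mean first-passage time by numerical quadrature
#'
#' Evaluates the steady-state-flux solution
#' `tau_a = int_{r0}^{rn} dr r^2 e^{-U(r)} int_{r0}^{r} dr' e^{U(r')} / (D(r') r'^2)`
#' by nested quadrature. Profiles default to the sigmoidal droplet forms;
#' arbitrary `D_fun(r)`, `U_fun(r)` may be supplied (with `breaks` listing
#' their discontinuities, e.g. `r_f` for sharp step profiles).
#'
#' @param spec A [search_spec()].
#' @param D_fun,U_fun Optional radial profile functions (um^2/s, kBT).
#' @param breaks Radii at which the profiles are non-smooth; integration is
#'   split there.
#' @param rel_tol Relative tolerance of each quadrature.
#' @return Mean first-passage time in seconds.
#' @export
mfpt_quadrature <- function(spec, D_fun = NULL, U_fun = NULL,
                            breaks = spec$geometry$r_f, rel_tol = 1e-8) {
  stopifnot(inherits(spec, "search_spec"))
  g <- spec$geometry
  if (is.null(D_fun)) {
    p <- as_lpm(spec)
    D_fun <- function(r) lpm_diffusivity(r, p)
    U_fun <- function(r) lpm_potential(r, p)
  }
  inner_f <- function(r) exp(U_fun(r)) / (D_fun(r) * r^2)
  pieces <- sort(unique(c(spec$r0, breaks[breaks > spec$r0 & breaks < g$r_n],
                          g$r_n)))
  seg_int <- function(f, lo, hi) {
    if (hi <= lo) return(0)
    integrate(f, lo, hi, rel.tol = rel_tol, subdivisions = 500L)$value
  }
  # cumulative inner integral up to each breakpoint
  cum <- c(0, cumsum(vapply(seq_len(length(pieces) - 1L), function(i)
    seg_int(inner_f, pieces[i], pieces[i + 1]), numeric(1))))
  inner <- function(r) {
    vapply(r, function(ri) {
      j <- findInterval(ri, pieces)
      j <- max(1L, min(j, length(pieces) - 1L))
      cum[j] + seg_int(inner_f, pieces[j], ri)
    }, numeric(1))
  }
  outer_f <- function(r) r^2 * exp(-U_fun(r)) * inner(r)
  sum(vapply(seq_len(length(pieces) - 1L), function(i)
    seg_int(outer_f, pieces[i], pieces[i + 1]), numeric(1)))
}

#' Mean first-passage time, sharp-boundary closed form
#'
#' Exact evaluation of the quadrature for step profiles (`b r_f >> 1`):
#' \deqn{\tau_a = \frac{r_f^3 - r_0^3}{3 D_0 r_0} + \frac{r_0^2 - r_f^2}{2 D_0}
#'  + e^{-A}\left(\frac{r_n^3 - r_f^3}{3 D_0 r_0} + \frac{r_f^3 - r_n^3}{3 D_0 r_f}\right)
#'  + \frac{r_n^3 - r_f^3}{3 D_n r_f} + \frac{r_f^2 - r_n^2}{2 D_n}.}
#' In the limit `r0 << r_f << r_n`, `A >> 1` this reduces to
#' `r_f^3/(3 D0 r0) + r_n^3/(3 Dn r_f)`: the time to find the focus plus the
#' time to find the target from the focus boundary.
#'
#' @param spec A [search_spec()].
#' @return Mean first-passage time in seconds.
#' @export
mfpt_closed_form <- function(spec) {
  stopifnot(inherits(spec, "search_spec"))
  r0 <- spec$r0; rf <- spec$geometry$r_f; rn <- spec$geometry$r_n
  D0 <- spec$D0; Dn <- spec$Dn; A <- spec$A
  if (!(r0 < rf && rf < rn)) stop("requires r0 < r_f < r_n")
  (rf^3 - r0^3) / (3 * D0 * r0) + (r0^2 - rf^2) / (2 * D0) +
    exp(-A) * ((rn^3 - rf^3) / (3 * D0 * r0) + (rf^3 - rn^3) / (3 * D0 * rf)) +
    (rn^3 - rf^3) / (3 * Dn * rf) + (rf^2 - rn^2) / (2 * Dn)
}

#' Optimal focus radius minimizing the search time
#'
#' In the droplet model, for `r_n >> r0` the interior minimum of the search
#' time over `r_f` is
#' `rf* = [r0 rn^3 (D0/Dn - e^{-A}) / (3 (1 - e^{-A}))]^{1/4}`, which exists
#' iff `D0 e^{A} > Dn` (the gain in occupancy outweighs the slower interior
#' diffusion). In the binding-site model the diffusivity-potential
#' constraint forces `rf* = [r0 rn^3 Db / (3 Dn)]^{1/4}`, which shrinks to 0
#' for immobile sites.
#'
#' @param r0 Target radius (um).
#' @param r_n Nucleus radius (um).
#' @param D0 In-focus diffusivity (droplet model, um^2/s).
#' @param Dn Nucleoplasm diffusivity (um^2/s).
#' @param A Potential depth (kBT, droplet model).
#' @param Db Binding-site diffusivity (binding-site model, um^2/s).
#' @param model `"LPM"` (droplet) or `"PBM"` (binding sites).
#' @return List with `r_f` (um, or `NA`), `exists`, and `reason` when no
#'   optimum exists.
#' @export
optimal_focus_radius <- function(r0, r_n, D0 = NULL, Dn = 1.0, A = NULL,
                                 Db = NULL, model = c("LPM", "PBM")) {
  model <- match.arg(model)
  if (model == "LPM") {
    stopifnot(!is.null(D0), !is.null(A))
    if (D0 * exp(A) <= Dn)
      return(list(r_f = NA_real_, exists = FALSE,
                  reason = "no interior optimum: D0 * exp(A) <= Dn"))
    rf4 <- r0 * r_n^3 * (D0 / Dn - exp(-A)) / (3 * (1 - exp(-A)))
    list(r_f = rf4^(1 / 4), exists = TRUE, reason = NULL)
  } else {
    stopifnot(!is.null(Db))
    if (Db <= 0)
      return(list(r_f = 0, exists = TRUE,
                  reason = "immobile sites: optimal focus size shrinks to 0"))
    list(r_f = (r0 * r_n^3 * Db / (3 * Dn))^(1 / 4), exists = TRUE,
         reason = NULL)
  }
}

#' Relative concentration-sensing error (generalized Berg-Purcell limit)
#'
#' Poisson counting noise on the `n ~ 4 pi c rn^3 t / (3 tau_a)` target
#' arrivals in an integration time `t` bounds the relative error on the
#' ligand concentration `c`:
#' * `"general"`: `sqrt(3 tau_a / (4 pi c rn^3 t))` with `tau_a` from
#'   [mfpt_closed_form()].
#' * `"large_nucleus"`: the `rn -> Inf` limit
#'   `sqrt((1/(4 pi c t)) (1/(Dn rf) + e^{-A}/D0 (1/r0 - 1/rf)))`; at
#'   `r0 = rf` this is the classic Berg-Purcell bound
#'   `1/sqrt(4 pi Dn c rf t)`.
#' * `"strong_potential"`: the optimal-focus regime
#'   `sqrt((1/(pi c t)) (pout/(4 pin D0 r0) + 1/(3 Dn rf)))` with
#'   `pout/pin = e^{-A}`.
#'
#' @param c_conc Ligand concentration (um^-3).
#' @param t Integration time (s).
#' @param spec A [search_spec()].
#' @param form Which expression to use.
#' @return Dimensionless relative error `dc/c`.
#' @export
sensing_relative_error <- function(c_conc, t, spec,
                                   form = c("general", "large_nucleus",
                                            "strong_potential")) {
  form <- match.arg(form)
  if (c_conc <= 0 || t <= 0) stop("c_conc and t must be positive")
  r0 <- spec$r0; rf <- spec$geometry$r_f; rn <- spec$geometry$r_n
  D0 <- spec$D0; Dn <- spec$Dn; A <- spec$A
  switch(form,
    general = sqrt(3 * mfpt_closed_form(spec) / (4 * pi * c_conc * rn^3 * t)),
    large_nucleus = sqrt((1 / (4 * pi * c_conc * t)) *
                           (1 / (Dn * rf) + exp(-A) / D0 * (1 / r0 - 1 / rf))),
    strong_potential = sqrt((1 / (pi * c_conc * t)) *
                              (exp(-A) / (4 * D0 * r0) + 1 / (3 * Dn * rf))))
}

#' Simulated first-passage times to the central target
#'
#' Runs `n_traj` independent trajectories of the droplet or binding-site
#' simulator until the tracer first enters the absorbing target sphere
#' `|r| <= r0`. The default start rule places the tracer on the nucleus
#' boundary with a random direction, which is the initial condition whose
#' mean matches the closed-form search time; `"equilibrium-outside-target"`
#' draws the starting radius from the Boltzmann law restricted to `r > r0`,
#' and `"uniform"` draws uniformly in the nucleus outside the target.
#'
#' @param spec A [search_spec()] (target and, for the droplet model, the
#'   profiles).
#' @param model_params An [lpm_params()] or [pbm_params()]; defaults to the
#'   droplet parameters in `spec`.
#' @param cfg A [sim_config()]; `n_steps` is the per-trajectory cap (default
#'   1e9), exceeding it censors the trajectory (`NA` + warning), never a
#'   silent truncation.
#' @param n_traj Number of trajectories.
#' @param start_rule `"nucleus-edge"`, `"equilibrium-outside-target"` or
#'   `"uniform"`.
#' @return List with `times` (s, `NA` = censored), `mean`, `sem`,
#'   `n_censored`.
#' @export
simulate_first_passage <- function(spec, model_params = NULL,
                                   cfg = sim_config(dt = 1e-6, n_steps = 1e9),
                                   n_traj = 1000L,
                                   start_rule = c("nucleus-edge",
                                                  "equilibrium-outside-target",
                                                  "uniform")) {
  stopifnot(inherits(spec, "search_spec"))
  start_rule <- match.arg(start_rule)
  if (is.null(model_params)) model_params <- as_lpm(spec)
  g <- model_params$geometry
  set.seed(cfg$seed)
  starts <- switch(start_rule,
    "nucleus-edge" = random_unit_vector(n_traj) * g$r_n * (1 - 1e-9),
    "equilibrium-outside-target" = {
      p <- if (inherits(model_params, "lpm_params")) model_params else
        lpm_params(g, D0 = model_params$Dn, Dn = model_params$Dn, A = 0)
      r <- sample_boltzmann_radius(p, n_traj, r_min = spec$r0)
      random_unit_vector(n_traj) * r
    },
    "uniform" = {
      m <- runif_ball(4L * n_traj, g$r_n)
      m <- m[sqrt(rowSums(m^2)) > spec$r0, , drop = FALSE]
      while (nrow(m) < n_traj)
        m <- rbind(m, runif_ball(2L * n_traj, g$r_n))
      m[seq_len(n_traj), , drop = FALSE]
    })
  if (inherits(model_params, "lpm_params")) {
    times <- cpp_fpt_lpm(starts, spec$r0, g$r_f, g$r_n, model_params$D0,
                         model_params$Dn, model_params$A, model_params$b,
                         cfg$dt, cfg$seed, cfg$n_steps)
  } else if (inherits(model_params, "pbm_params")) {
    pb <- check_pbm_stability(model_params, cfg)
    times <- cpp_fpt_pbm(starts, n_binding_sites(model_params), spec$r0,
                         g$r_f, g$r_n, model_params$Dn, model_params$Db,
                         model_params$r_b, pb, model_params$k_off,
                         cfg$dt, cfg$seed, cfg$n_steps)
  } else stop("model_params must be lpm_params or pbm_params")
  nc <- sum(is.na(times))
  if (nc > 0)
    warning(sprintf("%d of %d trajectories censored at the step cap", nc,
                    n_traj))
  tv <- times[!is.na(times)]
  list(times = times, mean = mean(tv), sem = sd(tv) / sqrt(length(tv)),
       n_censored = nc)
}
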