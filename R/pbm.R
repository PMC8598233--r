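# Event-resolved simulation of the binding-site (PBM) model.

#' Draw the initial binding-site configuration
#'
#' Places `N = round((4/3) pi rho r_f^3)` site centres uniformly in the focus
#' ball (sites are non-interacting and may overlap), plus `crowder_count`
#' inert spheres. Deterministic given `seed`.
#'
#' @param p A [pbm_params()].
#' @param seed Integer seed.
#' @return An object of class `"binding_sites"` with fields `centers`
#'   (N_total x 3 matrix, um), `n_bind` (number of absorbing sites; rows
#'   beyond `n_bind` are crowders), `bound_site_index` (`NA` = unbound) and
#'   `bound_offset`.
#' @export
init_binding_sites <- function(p, seed = 1L) {
  stopifnot(inherits(p, "pbm_params"))
  n <- n_binding_sites(p)
  if (n < 1) stop("parameters imply N = 0 binding sites")
  set.seed(seed)
  centers <- runif_ball(n + p$crowder_count, p$geometry$r_f)
  structure(list(centers = centers, n_bind = n,
                 bound_site_index = NA_integer_,
                 bound_offset = c(0, 0, 0)),
            class = "binding_sites")
}

runif_ball <- function(n, R) {
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    cand <- matrix(runif(3 * m, -R, R), m, 3)
    keep <- rowSums(cand^2) <= R^2
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), n - got)
    if (take > 0) out[got + seq_len(take), ] <- cand[seq_len(take), , drop = FALSE]
    got <- got + take
  }
  out
}

#' Add inert crowder spheres to a site configuration
#'
#' Crowders have radius `r_b`, diffuse at `Db`, and always reflect the tracer
#' (absorption probability 0). They model molecular crowding inside the
#' focus without contributing binding.
#'
#' @param state A `"binding_sites"` state.
#' @param p A [pbm_params()].
#' @param count Number of crowders to add (>= 0).
#' @return The updated state.
#' @export
add_crowders <- function(state, p, count) {
  stopifnot(inherits(state, "binding_sites"), count >= 0)
  if (count == 0) return(state)
  extra <- runif_ball(count, p$geometry$r_f)
  state$centers <- rbind(state$centers, extra)
  state
}

#' Advance binding sites by one diffusive step
#'
#' Each centre takes an isotropic Gaussian step of per-axis variance
#' `2 Db dt` and is reflected at the focus boundary `|c| = r_f`, which keeps
#' the stationary site density uniform in the focus ball. A bound tracer
#' inherits its site's displacement exactly (handled inside the simulator).
#'
#' @param state A `"binding_sites"` state.
#' @param p A [pbm_params()].
#' @param dt Time step (s).
#' @return The updated state.
#' @export
advance_sites <- function(state, p, dt) {
  stopifnot(inherits(state, "binding_sites"))
  if (p$Db <= 0) return(state)
  n <- nrow(state$centers)
  prop <- state$centers + matrix(rnorm(3 * n, sd = sqrt(2 * p$Db * dt)), n, 3)
  r <- sqrt(rowSums(prop^2))
  out <- (r > p$geometry$r_f)
  while (any(out)) {
    rnew <- abs(2 * p$geometry$r_f - r[out])
    prop[out, ] <- prop[out, , drop = FALSE] * (rnew / r[out])
    r[out] <- rnew
    out <- (r > p$geometry$r_f)
  }
  state$centers <- prop
  state
}

#' Simulate a tracer in the Polymer Bridging Model
#'
#' Per integration step: an unbound tracer takes a free step at `Dn`
#' (everywhere, including inside the focus); if the proposed position lies
#' within `r_b` of the nearest site centre it binds with probability
#' [absorption_probability()], otherwise it is reflected radially off that
#' site to distance `2 r_b - dr` and re-tested against the other sites. A
#' bound tracer rides its site rigidly (sites diffuse at `Db`, confined to
#' the focus) and releases with probability `k_off * dt`. The nucleus
#' boundary is reflecting. Deterministic given `cfg$seed`.
#'
#' @param p A [pbm_params()].
#' @param cfg A [sim_config()]; the stability conditions (absorption
#'   probability << 1, step length << `r_b`) are enforced.
#' @param start A 3-vector (um) inside the nucleus, or `"uniform"` for a
#'   uniform position in the nucleus.
#' @param sites Optional `"binding_sites"` state (e.g. with crowders added);
#'   default: freshly drawn from `cfg$seed`.
#' @return A `"trajectory"` with `bound` flags (1 while attached to a site)
#'   and the final site configuration in `attr(, "sites")`.
#' @export
simulate_pbm <- function(p, cfg, start = "uniform", sites = NULL) {
  stopifnot(inherits(p, "pbm_params"), inherits(cfg, "sim_config"))
  pb <- check_pbm_stability(p, cfg)
  if (is.null(sites)) {
    sites <- if (n_binding_sites(p) + p$crowder_count == 0)
      structure(list(centers = matrix(numeric(0), 0, 3), n_bind = 0L,
                     bound_site_index = NA_integer_,
                     bound_offset = c(0, 0, 0)), class = "binding_sites")
    else init_binding_sites(p, cfg$seed)
  }
  g <- p$geometry
  if (is.character(start)) {
    if (!identical(start, "uniform")) stop("start must be a 3-vector or \"uniform\"")
    set.seed(cfg$seed + 1L)
    start <- as.numeric(runif_ball(1, g$r_n))
  }
  if (sqrt(sum(start^2)) > g$r_n) stop("start position outside the nucleus")
  out <- cpp_simulate_pbm(start, sites$centers, sites$n_bind,
                          g$r_f, g$r_n, p$Dn, p$Db, p$r_b, pb, p$k_off,
                          cfg$dt, cfg$n_steps, cfg$record_every, cfg$seed,
                          FALSE, 0)
  tr <- new_trajectory(out$t, out$pos, bound = out$bound, params = p,
                       seed = cfg$seed, dt = cfg$dt,
                       record_every = cfg$record_every)
  attr(tr, "sites") <- out$sites
  tr
}

#' Simulate the PBM in bulk (infinite focus)
#'
#' Periodic cubic box filled with binding sites at density `rho`; the same
#' stepping rules as [simulate_pbm()] with periodic boundaries. Used to
#' isolate bulk effects (binding-induced angle asymmetry, bulk effective
#' diffusivity) from focus-boundary effects.
#'
#' @param p A [pbm_params()] (`geometry` is ignored except through `rho`).
#' @param cfg A [sim_config()].
#' @param box_size Box side length (um), must exceed `10 r_b`.
#' @return A `"trajectory"` with `bound` flags. Positions are unwrapped
#'   modulo the box, i.e. folded into `[-box/2, box/2)`.
#' @export
simulate_pbm_bulk <- function(p, cfg, box_size = 0.3) {
  stopifnot(inherits(p, "pbm_params"), inherits(cfg, "sim_config"))
  if (box_size < 10 * p$r_b) stop("box_size must be at least 10 * r_b")
  pb <- check_pbm_stability(p, cfg)
  n <- round(p$rho * box_size^3)
  set.seed(cfg$seed)
  centers <- matrix(runif(3 * n, -box_size / 2, box_size / 2), n, 3)
  start <- c(0, 0, 0)
  out <- cpp_simulate_pbm(start, centers, n,
                          p$geometry$r_f, p$geometry$r_n, p$Dn, p$Db, p$r_b,
                          pb, p$k_off, cfg$dt, cfg$n_steps, cfg$record_every,
                          cfg$seed, TRUE, box_size)
  tr <- new_trajectory(out$t, out$pos, bound = out$bound, params = p,
                       seed = cfg$seed, dt = cfg$dt,
                       record_every = cfg$record_every)
  attr(tr, "box") <- box_size
  tr
}

#' Unwrap a periodic (bulk-mode) trajectory
#'
#' Reconstructs continuous coordinates from box-folded positions by applying
#' the minimum-image convention to successive frame displacements. Valid as
#' long as no per-frame displacement exceeds half the box.
#'
#' @param tr A trajectory from [simulate_pbm_bulk()].
#' @return The trajectory with continuous (unwrapped) positions.
#' @export
unwrap_trajectory <- function(tr) {
  box <- attr(tr, "box")
  if (is.null(box)) return(tr)
  d <- diff(tr$pos)
  d <- d - box * round(d / box)
  if (mean(abs(d) > 0.4 * box) > 1e-3)
    warning("frame displacements approach half the box; unwrapping is unreliable - record more densely")
  tr$pos <- rbind(tr$pos[1, , drop = FALSE],
                  sweep(apply(d, 2, cumsum), 2, tr$pos[1, ], "+"))
  colnames(tr$pos) <- c("x", "y", "z")
  attr(tr, "box") <- NULL
  tr
}
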