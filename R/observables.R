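# Track-level estimators: the measurement model and the observables used to
# compare the droplet and binding-site pictures (displacement statistics,
# radial diffusivity/density profiles, mean radial displacement, angles).
#
# Track tables are plain data.frames with columns track_id, frame (0-based,
# contiguous within a track), t_s, x_um, y_um and optional z_um, bound.

#' Convert a simulated trajectory to a track table
#'
#' @param traj A `"trajectory"`.
#' @param track_id Identifier for the single track.
#' @return A track table with `z_um` (and `bound` if present).
#' @export
as_track_table <- function(traj, track_id = "traj1") {
  stopifnot(inherits(traj, "trajectory"))
  out <- data.frame(track_id = track_id,
                    frame = seq_along(traj$t) - 1L,
                    t_s = traj$t,
                    x_um = traj$pos[, 1],
                    y_um = traj$pos[, 2],
                    z_um = traj$pos[, 3],
                    stringsAsFactors = FALSE)
  if (!is.null(traj$bound)) out$bound <- as.integer(traj$bound)
  out
}

track_dim <- function(tracks) if ("z_um" %in% names(tracks)) 3L else 2L

#' Imaging measurement model
#'
#' Turns an ideal 3D trajectory into what a tracking microscope records:
#' subsample to the frame interval `dt_obs`, keep only frames inside the
#' visible z-slab (`|z| <= z_slab`), split at the resulting gaps into
#' separate tracks, project to (x, y), and add i.i.d. Gaussian localization
#' noise of standard deviation `sigma` per axis. Defaults mirror a 50 Hz
#' acquisition with 30 nm localization noise and a +/- 150 nm z-slab.
#'
#' @param traj A `"trajectory"`.
#' @param sigma Localization noise SD per axis (um).
#' @param dt_obs Frame interval (s); must be an integer multiple of the
#'   trajectory's recorded spacing.
#' @param z_slab Half-thickness of the visible slab (um); `Inf` keeps all.
#' @param seed Seed for the noise draws.
#' @return A 2D track table (`track_id`, `frame`, `t_s`, `x_um`, `y_um`).
#' @export
apply_measurement_model <- function(traj, sigma = 0.03, dt_obs = 0.02,
                                    z_slab = 0.15, seed = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$t) < 2) stop("trajectory too short")
  spacing <- traj$t[2] - traj$t[1]
  k <- dt_obs / spacing
  if (abs(k - round(k)) > 1e-6)
    stop("dt_obs is not an integer multiple of the recorded spacing")
  k <- as.integer(round(k))
  idx <- seq(1L, nrow(traj$pos), by = k)
  pos <- traj$pos[idx, , drop = FALSE]
  tt <- traj$t[idx]
  keep <- abs(pos[, 3]) <= z_slab
  if (!any(keep)) stop("no frames inside the z-slab")
  # split kept frames into maximal consecutive runs
  kept_idx <- which(keep)
  brk <- cumsum(c(1L, as.integer(diff(kept_idx) != 1L)))
  set.seed(seed)
  n <- length(kept_idx)
  noise <- if (sigma > 0) matrix(rnorm(2 * n, sd = sigma), n, 2) else
    matrix(0, n, 2)
  out <- data.frame(track_id = sprintf("t%04d", brk),
                    frame = unlist(lapply(split(kept_idx, brk),
                                          function(v) seq_along(v) - 1L),
                                   use.names = FALSE),
                    t_s = tt[kept_idx],
                    x_um = pos[kept_idx, 1] + noise[, 1],
                    y_um = pos[kept_idx, 2] + noise[, 2],
                    stringsAsFactors = FALSE)
  out
}

# displacements at integer frame lag within tracks; returns start coords,
# displacement components and the lag time
track_displacements <- function(tracks, lag = 1L) {
  d <- track_dim(tracks)
  o <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  n <- nrow(o)
  if (n <= lag) stop("not enough frames for this lag")
  i0 <- seq_len(n - lag)
  i1 <- i0 + lag
  ok <- o$track_id[i0] == o$track_id[i1] & (o$frame[i1] - o$frame[i0]) == lag
  i0 <- i0[ok]; i1 <- i1[ok]
  if (!length(i0)) stop("no displacements at this lag")
  res <- data.frame(x0 = o$x_um[i0], y0 = o$y_um[i0],
                    dx = o$x_um[i1] - o$x_um[i0],
                    dy = o$y_um[i1] - o$y_um[i0])
  if (d == 3L) {
    res$z0 <- o$z_um[i0]
    res$dz <- o$z_um[i1] - o$z_um[i0]
  }
  attr(res, "dt_lag") <- (o$t_s[i1] - o$t_s[i0])[1]
  attr(res, "d") <- d
  res
}

radius_from_center <- function(x, y, z = NULL, center) {
  if (is.null(z)) sqrt((x - center[1])^2 + (y - center[2])^2)
  else sqrt((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2)
}

#' Displacement (jump-size) histogram with single-diffusivity overlay
#'
#' Builds the empirical distribution of displacement magnitudes `|dr|` at a
#' frame lag and fits the free-diffusion reference at the maximum-likelihood
#' diffusivity `D = <|dr|^2> / (2 d dt)`. For 2D tracks the reference is the
#' Rayleigh-type density `p(u) = u/(2 D dt) exp(-u^2/(4 D dt))`; for 3D
#' trajectories the corresponding 3D (Maxwell) form is used. A KS test
#' against the fitted reference flags departures from Gaussian displacements
#' (e.g. the near-zero peak produced by slow binding/unbinding).
#'
#' @param tracks A track table.
#' @param lag Frame lag.
#' @param bins Number of histogram bins.
#' @return List with `displacements`, `D_fit`, `dt_lag`, `d`, `hist`
#'   (data.frame mid/density/theory) and `ks` (the `htest`).
#' @export
displacement_histogram <- function(tracks, lag = 1L, bins = 40L) {
  dd <- track_displacements(tracks, lag)
  d <- attr(dd, "d"); dt_lag <- attr(dd, "dt_lag")
  u <- if (d == 2L) sqrt(dd$dx^2 + dd$dy^2) else sqrt(dd$dx^2 + dd$dy^2 + dd$dz^2)
  if (length(u) < 100) stop("need at least 100 displacements")
  D <- mean(u^2) / (2 * d * dt_lag)
  s2 <- 2 * D * dt_lag  # per-axis variance
  cdf <- if (d == 2L) function(q) 1 - exp(-q^2 / (2 * s2)) else
    function(q) pchisq(q^2 / s2, df = 3)
  pdf <- if (d == 2L) function(q) q / s2 * exp(-q^2 / (2 * s2)) else
    function(q) sqrt(2 / pi) * q^2 / s2^(3 / 2) * exp(-q^2 / (2 * s2))
  ks <- suppressWarnings(ks.test(u, cdf))
  h <- hist(u, breaks = bins, plot = FALSE)
  list(displacements = u, D_fit = D, dt_lag = dt_lag, d = d,
       hist = data.frame(mid = h$mids, density = h$density,
                         theory = pdf(h$mids)),
       ks = ks)
}

#' @importFrom stats pchisq
#' @importFrom graphics hist
NULL

#' Detectability map of non-Gaussian displacements in the PBM
#'
#' For each combination of observation interval and unbinding rate, simulates
#' the PBM in bulk mode (constant site density, no boundary), projects to 2D
#' with localization noise, and runs a two-sided KS test of the in-focus
#' displacement distribution against the free-diffusion reference at the
#' matched effective diffusivity. Binding is detectable when exchange is slow
#' on the observation timescale (`k_off * dt_obs` small) and is degraded by
#' measurement noise.
#'
#' @param p A [pbm_params()] (its `k_off` is overridden by the grid).
#' @param dt_obs_grid Observation intervals (s); must be multiples of the
#'   smallest one.
#' @param k_off_grid Unbinding rates (s^-1).
#' @param sigma Localization noise SD (um).
#' @param n_disp Displacements per grid point.
#' @param seed Integer seed.
#' @param alpha Significance level for the detectability flag.
#' @param box_size Bulk box side (um).
#' @return data.frame with `dt_obs`, `k_off`, `statistic`, `p_value`,
#'   `detectable`.
#' @export
ks_detectability <- function(p, dt_obs_grid, k_off_grid, sigma = 0.03,
                             n_disp = 2000L, seed = 1L, alpha = 0.05,
                             box_size = 0.2) {
  if (!length(dt_obs_grid) || !length(k_off_grid)) stop("empty grid")
  base <- min(dt_obs_grid)
  if (any(abs(dt_obs_grid / base - round(dt_obs_grid / base)) > 1e-9))
    stop("dt_obs_grid values must be multiples of the smallest")
  # record densely enough that no frame displacement approaches half the
  # box (min-image unwrapping would corrupt the tails otherwise)
  base_rec <- min(base, (box_size / 10)^2 / (2 * p$Dn))
  base_rec <- base / ceiling(base / base_rec)
  out <- list()
  for (ko in k_off_grid) {
    pk <- p; pk$k_off <- ko
    dt <- pbm_stable_dt(pk)
    rec <- max(1L, as.integer(round(base_rec / dt)))
    dt <- base_rec / rec
    need <- (max(dt_obs_grid) / base_rec) * (n_disp + 1L)
    cfg <- sim_config(dt = dt, n_steps = need * rec, seed = seed,
                      record_every = rec)
    tr <- unwrap_trajectory(simulate_pbm_bulk(pk, cfg, box_size))
    set.seed(seed + 17L)
    xy <- tr$pos[, 1:2] + matrix(rnorm(2 * nrow(tr$pos), sd = sigma),
                                 ncol = 2)
    for (dto in dt_obs_grid) {
      k <- as.integer(round(dto / base_rec))
      idx <- seq(1L, nrow(xy), by = k)
      u <- sqrt(diff(xy[idx, 1])^2 + diff(xy[idx, 2])^2)
      u <- u[seq_len(min(length(u), n_disp))]
      s2 <- mean(u^2) / 2
      ks <- suppressWarnings(ks.test(u, function(q) 1 - exp(-q^2 / (2 * s2))))
      out[[length(out) + 1L]] <-
        data.frame(dt_obs = dto, k_off = ko,
                   statistic = unname(ks$statistic), p_value = ks$p.value,
                   detectable = ks$p.value < alpha)
    }
  }
  do.call(rbind, out)
}

new_radial_profile <- function(edges, value, se, n, kind) {
  structure(data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
                       value = value, se = se, n = n),
            bin_edges = edges, kind = kind, class = c("radial_profile", "data.frame"))
}

#' Radial effective-diffusivity profile
#'
#' Bins displacements by their start distance to the focus centre and
#' estimates `D(r) = <|dr|^2> / (2 d dt)` per bin (`d = 2` for projected
#' tracks, 3 for full trajectories). With `sigma` given, the localization
#' noise floor `2 sigma^2` per axis is subtracted from the MSD before
#' division. Empty bins are reported with `NA` value, never interpolated.
#'
#' @param tracks A track table.
#' @param center Focus centre (2- or 3-vector, um).
#' @param bin_width Radial bin width (um).
#' @param lag Frame lag used for displacements.
#' @param sigma Optional localization noise SD (um) for the correction.
#' @param r_max Outer edge of the binning (default: max start radius).
#' @return A `"radial_profile"` data.frame (`r`, `value`, `se`, `n`).
#' @export
radial_diffusivity_profile <- function(tracks, center = c(0, 0, 0),
                                       bin_width = 1e-3, lag = 1L,
                                       sigma = NULL, r_max = NULL) {
  dd <- track_displacements(tracks, lag)
  d <- attr(dd, "d"); dt_lag <- attr(dd, "dt_lag")
  r0 <- radius_from_center(dd$x0, dd$y0, dd$z0, center)
  dr2 <- if (d == 2L) dd$dx^2 + dd$dy^2 else dd$dx^2 + dd$dy^2 + dd$dz^2
  corr <- if (is.null(sigma)) 0 else d * 2 * sigma^2
  if (is.null(r_max)) r_max <- max(r0)
  edges <- seq(0, r_max + bin_width, by = bin_width)
  bin <- findInterval(r0, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  val <- se <- rep(NA_real_, nb); n <- integer(nb)
  for (b in unique(bin)) {
    if (b < 1 || b > nb) next
    v <- dr2[bin == b]
    n[b] <- length(v)
    val[b] <- (mean(v) - corr) / (2 * d * dt_lag)
    se[b] <- if (n[b] > 1) sd(v) / sqrt(n[b]) / (2 * d * dt_lag) else NA_real_
  }
  pr <- new_radial_profile(edges, val, se, n, "diffusivity")
  attr(pr, "d") <- d; attr(pr, "dt_lag") <- dt_lag
  pr
}

#' Radial particle-density profile
#'
#' Occupancy per radial bin divided by the bin's geometric volume: spherical
#' shells for 3D trajectories; for 2D slab data, annulus area times slab
#' thickness `2 z_slab` (the numerical deprojection factor), the estimate
#' being attributed to the mean 3D radius `sqrt(s^2 + z_slab^2/3)` of each
#' annulus. Normalized so the density integrates to one over the binned
#' region.
#'
#' @inheritParams radial_diffusivity_profile
#' @param z_slab Half-thickness of the visible slab (um) for 2D tracks;
#'   ignored for 3D tracks.
#' @return A `"radial_profile"` data.frame.
#' @export
radial_density_profile <- function(tracks, center = c(0, 0, 0),
                                   bin_width = 1e-3, z_slab = NULL,
                                   r_max = NULL) {
  d <- track_dim(tracks)
  r <- if (d == 3L) radius_from_center(tracks$x_um, tracks$y_um, tracks$z_um, center)
  else radius_from_center(tracks$x_um, tracks$y_um, NULL, center)
  if (is.null(r_max)) r_max <- max(r)
  edges <- seq(0, r_max + bin_width, by = bin_width)
  nb <- length(edges) - 1L
  cnt <- tabulate(findInterval(r, edges, rightmost.closed = TRUE), nbins = nb)
  if (d == 3L) {
    vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
    mid <- (edges[-1] + edges[-length(edges)]) / 2
  } else {
    area <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
    thick <- if (is.null(z_slab) || !is.finite(z_slab)) 1 else 2 * z_slab
    vol <- area * thick
    s_mid <- (edges[-1] + edges[-length(edges)]) / 2
    mid <- if (is.null(z_slab) || !is.finite(z_slab)) s_mid else
      sqrt(s_mid^2 + z_slab^2 / 3)
  }
  ntot <- sum(cnt)
  val <- cnt / (ntot * vol)
  se <- sqrt(pmax(cnt, 1)) / (ntot * vol)
  pr <- new_radial_profile(edges, val, se, cnt, "density")
  pr$r <- mid
  attr(pr, "d") <- d
  pr
}

#' Binned mean radial displacement
#'
#' For each bin of the starting radius, the mean of `r(t + lag) - r(t)` with
#' its standard error. In the binding-site model with immobile sites this
#' curve cannot be negative; an inward dip at the focus boundary is the
#' droplet signature.
#'
#' @inheritParams radial_diffusivity_profile
#' @return A `"radial_profile"` data.frame.
#' @export
mean_radial_displacement <- function(tracks, center = c(0, 0, 0),
                                     bin_width = 1e-3, lag = 1L,
                                     r_max = NULL) {
  dd <- track_displacements(tracks, lag)
  d <- attr(dd, "d"); dt_lag <- attr(dd, "dt_lag")
  r0 <- radius_from_center(dd$x0, dd$y0, dd$z0, center)
  r1 <- if (d == 2L)
    radius_from_center(dd$x0 + dd$dx, dd$y0 + dd$dy, NULL, center)
  else radius_from_center(dd$x0 + dd$dx, dd$y0 + dd$dy, dd$z0 + dd$dz, center)
  dr <- r1 - r0
  if (is.null(r_max)) r_max <- max(r0)
  edges <- seq(0, r_max + bin_width, by = bin_width)
  bin <- findInterval(r0, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  val <- se <- rep(NA_real_, nb); n <- integer(nb)
  for (b in unique(bin)) {
    if (b < 1 || b > nb) next
    v <- dr[bin == b]
    n[b] <- length(v)
    val[b] <- mean(v)
    se[b] <- if (n[b] > 1) sd(v) / sqrt(n[b]) else NA_real_
  }
  pr <- new_radial_profile(edges, val, se, n, "radial_displacement")
  attr(pr, "d") <- d; attr(pr, "dt_lag") <- dt_lag
  pr
}

#' Maximal positive difference between observed and PBM-predicted drift
#'
#' Computes the binding-site-model prediction for the mean radial
#' displacement from the *measured* diffusivity and density profiles
#' ([predicted_radial_drift()]) and returns the largest positive excess of
#' the observed drift over the prediction in the boundary window
#' `[0.5 r_f, 1.5 r_f]`. For data generated by the binding-site model this
#' statistic is consistent with zero; a droplet with fast interior diffusion
#' produces a significantly positive value, rejecting the binding-site
#' model.
#'
#' @param tracks A track table.
#' @param center Focus centre.
#' @param Db_assumed Site diffusivity assumed in the prediction (um^2/s).
#' @param r_f Focus radius (um) defining the search window.
#' @param bin_width Radial bin width (um).
#' @param lag Frame lag.
#' @param min_n Minimum displacements per bin for inclusion.
#' @return List with `mpd` (um), `r_at`, `se` (combined SE at the maximising
#'   bin) and the per-bin `table`.
#' @export
maximal_positive_difference <- function(tracks, center = c(0, 0, 0),
                                        Db_assumed = 0.005, r_f,
                                        bin_width = 5e-3, lag = 1L,
                                        min_n = 20L) {
  obs <- mean_radial_displacement(tracks, center, bin_width, lag)
  dif <- radial_diffusivity_profile(tracks, center, bin_width, lag)
  den <- radial_density_profile(tracks, center, bin_width)
  d <- attr(obs, "d"); dt_lag <- attr(obs, "dt_lag")
  m <- min(nrow(obs), nrow(dif), nrow(den))
  keep <- seq_len(m)
  ok <- is.finite(obs$value[keep]) & is.finite(dif$value[keep]) &
    is.finite(den$value[keep]) & den$value[keep] > 0 &
    obs$n[keep] >= min_n & dif$value[keep] > Db_assumed
  if (sum(ok) < 5) stop("insufficient boundary statistics for the comparison")
  prof <- list(r = obs$r[keep][ok], D = dif$value[keep][ok],
               p = den$value[keep][ok], D_se = dif$se[keep][ok],
               p_se = den$se[keep][ok])
  pred <- predicted_radial_drift(prof, dt_lag, d = d)
  diff_curve <- obs$value[keep][ok] - pred$drift
  se_comb <- sqrt(obs$se[keep][ok]^2 + ifelse(is.na(pred$se), 0, pred$se)^2)
  win <- prof$r >= 0.5 * r_f & prof$r <= 1.5 * r_f
  if (!any(win)) stop("no usable bins in the boundary window")
  i <- which(win)[which.max(diff_curve[win])]
  list(mpd = diff_curve[i], r_at = prof$r[i], se = se_comb[i],
       table = data.frame(r = prof$r, observed = obs$value[keep][ok],
                          predicted = pred$drift, difference = diff_curve,
                          se = se_comb, in_window = win))
}

#' Distribution of angles between consecutive displacements
#'
#' The angle between the vector joining the first two points and the vector
#' joining the last two points of each frame triplet, in degrees on
#' \[0, 180\]. Uniform for free diffusion in a homogeneous environment;
#' confinement and obstacles enrich motion reversals (angles near 180).
#' Zero-length displacements are skipped.
#'
#' @param tracks A track table (angles use the observed dimension).
#' @param nbins Number of histogram bins over \[0, 180\].
#' @return List with `breaks`, `counts`, `density` (per degree),
#'   `asymmetry` (fraction in \[150, 180\] over fraction in \[0, 30\]) and
#'   `chisq` (uniformity test).
#' @export
angle_distribution <- function(tracks, nbins = 18L) {
  d <- track_dim(tracks)
  o <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  n <- nrow(o)
  if (n < 3) stop("need tracks with at least 3 consecutive frames")
  i0 <- seq_len(n - 2L); i1 <- i0 + 1L; i2 <- i0 + 2L
  ok <- o$track_id[i0] == o$track_id[i2] &
    (o$frame[i2] - o$frame[i0]) == 2L
  cols <- if (d == 3L) c("x_um", "y_um", "z_um") else c("x_um", "y_um")
  a <- as.matrix(o[i1[ok], cols]) - as.matrix(o[i0[ok], cols])
  b <- as.matrix(o[i2[ok], cols]) - as.matrix(o[i1[ok], cols])
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  good <- na > 0 & nb > 0
  cosang <- pmin(1, pmax(-1, rowSums(a * b)[good] / (na[good] * nb[good])))
  ang <- acos(cosang) * 180 / pi
  breaks <- seq(0, 180, length.out = nbins + 1L)
  cnt <- tabulate(findInterval(ang, breaks, rightmost.closed = TRUE),
                  nbins = nbins)
  asym <- mean(ang >= 150) / max(mean(ang <= 30), 1e-12)
  chisq <- suppressWarnings(chisq.test(cnt))
  list(angles = ang, breaks = breaks, counts = cnt,
       density = cnt / sum(cnt) / diff(breaks)[1],
       asymmetry = asym, chisq = chisq)
}

#' Two-population Gaussian mixture fit of per-axis displacements
#'
#' Pools per-axis displacements across tracks and fits a two-component
#' zero-mean Gaussian scale mixture by EM, modelling a slow (in-focus) and a
#' fast (nucleoplasm) population. Component variances are converted to
#' diffusivities via the localization-noise-corrected relation
#' `var = 2 D dt + 2 sigma^2` per axis.
#'
#' @param tracks A track table.
#' @param sigma Localization noise SD per axis (um); 0 disables the
#'   correction.
#' @param dt_obs Frame interval (s); default read from the data.
#' @param lag Frame lag.
#' @param max_iter,tol EM controls.
#' @return List with `D_slow`, `D_fast`, `weight_slow`, `converged`,
#'   `degenerate` (TRUE when one component suffices; then both D estimates
#'   coincide), `loglik`.
#' @export
fit_two_population_displacements <- function(tracks, sigma = 0, dt_obs = NULL,
                                             lag = 1L, max_iter = 1000L,
                                             tol = 1e-10) {
  dd <- track_displacements(tracks, lag)
  if (is.null(dt_obs)) dt_obs <- attr(dd, "dt_lag")
  x <- c(dd$dx, dd$dy)
  v <- stats::var(x)
  v1 <- v / 4; v2 <- v * 2; w <- 0.5
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    f1 <- w * stats::dnorm(x, 0, sqrt(v1))
    f2 <- (1 - w) * stats::dnorm(x, 0, sqrt(v2))
    tot <- f1 + f2
    g <- f1 / tot
    w <- mean(g)
    v1 <- sum(g * x^2) / sum(g)
    v2 <- sum((1 - g) * x^2) / sum(1 - g)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll)) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (v1 > v2) { tmp <- v1; v1 <- v2; v2 <- tmp; w <- 1 - w }
  degenerate <- (v2 - v1) / v2 < 0.05 || w < 0.02 || w > 0.98
  to_D <- function(vv) (vv - 2 * sigma^2) / (2 * dt_obs)
  if (degenerate) {
    D <- to_D(v)
    out <- list(D_slow = D, D_fast = D, weight_slow = 1, converged = converged,
                degenerate = TRUE, loglik = ll)
  } else {
    out <- list(D_slow = to_D(v1), D_fast = to_D(v2), weight_slow = w,
                converged = converged, degenerate = FALSE, loglik = ll)
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (loglik %.6g)",
                    max_iter, ll))
  out
}

#' Estimate focus centre, radius and droplet parameters from tracks
#'
#' The centre is the density-weighted mode of the positions (per-axis kernel
#' density peaks, refined by the centroid of nearby points); the focus
#' radius is the half-enhancement crossing of the radial density; `D0` is
#' the mean diffusivity plateau at `r < 0.8 r_f`; the potential depth is
#' `A = ln(pin/pout)` from the density plateaus inside (`< 0.8 r_f`) and
#' outside (`> 1.5 r_f`). Errors if no density enhancement is present.
#'
#' @param tracks A track table.
#' @param bin_width Radial bin width (um).
#' @param lag Frame lag for the diffusivity profile.
#' @param min_enhancement Minimum pin/pout ratio for a focus call.
#' @return List with `center`, `r_f`, `D0`, `A`.
#' @export
estimate_focus_center_and_params <- function(tracks, bin_width = 5e-3,
                                             lag = 1L, min_enhancement = 2) {
  d <- track_dim(tracks)
  cols <- if (d == 3L) c("x_um", "y_um", "z_um") else c("x_um", "y_um")
  center <- vapply(cols, function(cl) {
    dn <- stats::density(tracks[[cl]], n = 512)
    dn$x[which.max(dn$y)]
  }, numeric(1))
  r_all <- radius_from_center(tracks$x_um, tracks$y_um,
                              if (d == 3L) tracks$z_um else NULL, center)
  near <- r_all < stats::quantile(r_all, 0.2)
  center <- colMeans(as.matrix(tracks[near, cols, drop = FALSE]))
  den <- radial_density_profile(tracks, center, bin_width)
  okd <- is.finite(den$value) & den$n > 0
  rr <- den$r[okd]; pv <- den$value[okd]; nn <- den$n[okd]
  # count-weighted aggregate densities, robust to sparse innermost bins
  agg <- function(sel) if (any(sel)) sum(pv[sel] * nn[sel]) / sum(nn[sel])
  else NA_real_
  pin0 <- agg(rr < stats::quantile(r_all, 0.1))
  pout0 <- agg(rr > stats::quantile(r_all, 0.6))
  if (!is.finite(pin0) || !is.finite(pout0) || pin0 / pout0 < min_enhancement)
    stop("no focus: no density enhancement detected")
  half <- pout0 + (pin0 - pout0) / 2
  sm <- stats::filter(pv, rep(1 / 3, 3), sides = 2)  # light 3-bin smooth
  sm[is.na(sm)] <- pv[is.na(sm)]
  below <- which(sm < half & rr > rr[which.max(sm)])
  if (!length(below)) stop("no focus: density never decays to half-enhancement")
  i <- below[1]
  r_f <- if (i > 1) approx(sm[c(i - 1, i)], rr[c(i - 1, i)], xout = half)$y
  else rr[i]
  pin <- agg(rr < 0.8 * r_f)
  pout <- agg(rr > 1.5 * r_f)
  dif <- radial_diffusivity_profile(tracks, center, bin_width, lag)
  okD <- is.finite(dif$value) & dif$n >= 10
  D0 <- stats::weighted.mean(dif$value[okD & dif$r < 0.8 * r_f],
                             dif$n[okD & dif$r < 0.8 * r_f])
  list(center = unname(center), r_f = r_f, D0 = D0, A = log(pin / pout))
}
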