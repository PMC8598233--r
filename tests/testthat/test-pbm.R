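test_that("binding sites initialize uniformly in the focus, deterministically", {
  p <- pbm_params(geometry(0.1, 0.5), rho = 4.8e4)
  s1 <- init_binding_sites(p, seed = 5L)
  s2 <- init_binding_sites(p, seed = 5L)
  expect_identical(s1$centers, s2$centers)
  expect_equal(nrow(s1$centers), 201L)
  expect_true(all(rowSums(s1$centers^2) <= 0.1^2))
  # r^3 should be uniform for a uniform-in-ball law
  r3 <- (sqrt(rowSums(s1$centers^2)) / 0.1)^3
  cnt <- tabulate(findInterval(r3, seq(0, 1, 0.25), rightmost.closed = TRUE), 4)
  expect_gt(suppressWarnings(stats::chisq.test(cnt)$p.value), 0.01)
  expect_error(init_binding_sites(pbm_params(geometry(0.02, 0.5), rho = 100,
                                             r_b = 0.005)), "N = 0")
})

test_that("site advancement is Brownian, confined, and freezes at Db = 0", {
  p <- pbm_params(geometry(0.1, 0.5), Db = 0.005)
  s <- init_binding_sites(p, seed = 2L)
  p0 <- pbm_params(geometry(0.1, 0.5), Db = 0)
  expect_identical(advance_sites(s, p0, 1e-3)$centers, s$centers)
  # one coarse step: per-axis variance 2 Db dt (interior sites, no reflection)
  set.seed(11)
  dt <- 1e-4
  s2 <- advance_sites(s, p, dt)
  d <- s2$centers - s$centers
  expect_equal(stats::var(as.vector(d)), 2 * 0.005 * dt, tolerance = 0.15)
  # repeated stepping keeps all sites inside and the density uniform
  set.seed(12)
  for (i in 1:400) s2 <- advance_sites(s2, p, 1e-3)
  expect_true(all(rowSums(s2$centers^2) <= 0.1^2 + 1e-12))
  r3 <- (sqrt(rowSums(s2$centers^2)) / 0.1)^3
  cnt <- tabulate(findInterval(r3, seq(0, 1, 0.25), rightmost.closed = TRUE), 4)
  expect_gt(suppressWarnings(stats::chisq.test(cnt)$p.value), 0.01)
})

test_that("with no binding sites the tracer diffuses freely", {
  p <- pbm_params(geometry(0.1, 50), rho = 0, kappa = 1e-9)
  tr <- simulate_pbm(p, sim_config(1e-6, 1e5, 3L, 1L), start = c(0, 0, 0))
  expect_true(all(tr$bound == 0))
  v <- apply(diff(tr$pos, lag = 10), 2, stats::var)
  expect_equal(unname(v), rep(2 * 1 * 1e-5, 3), tolerance = 0.04)
})

test_that("bulk bound-time fraction follows surface-exchange detailed balance", {
  # reaction-limited regime: kappa r_b / Dn = 0.05, rebinding correction ~5%
  p <- pbm_params(geometry(0.1, 0.5), Dn = 1, Db = 0, rho = 4.8e4,
                  r_b = 0.01, kappa = 5, k_off = 250)
  dt <- pbm_stable_dt(p)
  cfg <- sim_config(dt, round(5 / dt), 19L, max(1L, round(1e-3 / dt)))
  tr <- simulate_pbm_bulk(p, cfg, box_size = 0.15)
  fb <- mean(tr$bound)
  odds <- 4 * pi * p$r_b^2 * p$kappa * p$rho / p$k_off
  expect_equal(fb, odds / (1 + odds), tolerance = 0.08)
  # ... and agrees with the Smoluchowski mean-field value in this regime
  kp <- smoluchowski_k_plus(1, 0.01, 5)
  expect_equal(fb, 1 - p_unbound(4.8e4, kp, 250), tolerance = 0.10)
})

test_that("rebinding renormalizes the equilibrium by 1 + kappa r_b / Dn", {
  # diffusion-influenced regime: kappa r_b / Dn = 1, so the microscopic
  # equilibrium doubles the Smoluchowski mean-field odds
  p <- pbm_params(geometry(0.1, 0.5), Dn = 1, Db = 0, rho = 4.8e4,
                  r_b = 0.01, kappa = 100, k_off = 500)
  dt <- pbm_stable_dt(p, pb_max = 0.2)
  cfg <- sim_config(dt, round(3 / dt), 23L, max(1L, round(1e-3 / dt)))
  tr <- simulate_pbm_bulk(p, cfg, box_size = 0.15)
  fb <- mean(tr$bound)
  enh <- pbm_equilibrium_enhancement(p)           # 1 + 12.06
  expect_equal(fb, 1 - 1 / enh, tolerance = 0.05)
  fb_smol <- 1 - p_unbound(4.8e4, smoluchowski_k_plus(1, 0.01, 100), 500)
  expect_gt(abs(fb - fb_smol), 0.03)              # renormalization is visible
})

test_that("bulk effective diffusivity is the occupancy-weighted average", {
  # dilute, reaction-limited regime (site volume fraction ~3%, kappa r_b/Dn
  # = 0.05), where the mean-field description is quantitative
  p <- pbm_params(geometry(0.1, 0.5), Dn = 1, Db = 0.005, rho = 8e3,
                  r_b = 0.01, kappa = 5, k_off = 50)
  dt <- pbm_stable_dt(p)
  rec <- max(1L, round(1e-4 / dt))
  cfg <- sim_config(dt, round(30 / dt), 29L, rec)
  tr <- unwrap_trajectory(simulate_pbm_bulk(p, cfg, box_size = 0.2))
  pu <- 1 - mean(tr$bound)
  n <- nrow(tr$pos)
  d2 <- rowSums((tr$pos[-(1:10), ] - tr$pos[1:(n - 10), ])^2)  # 1 ms lag
  D_meas <- mean(d2) / (6e-3)
  expect_equal(D_meas, effective_diffusivity(pu, 1, 0.005), tolerance = 0.05)
  # mean-field prediction from the rate constants holds in this regime
  enh <- pbm_equilibrium_enhancement(p)
  expect_equal(D_meas, effective_diffusivity(1 / enh, 1, 0.005),
               tolerance = 0.07)
})

test_that("fast exchange drives the occupancy ratio toward the weak-binding law", {
  g <- geometry(0.1, 0.2)
  p <- pbm_params(g, Dn = 1, Db = 0.005, rho = 4.8e4, r_b = 0.01,
                  kappa = 100, k_off = 2e4)
  dt <- pbm_stable_dt(p, pb_max = 0.2)
  rec <- max(1L, round(5e-4 / dt))
  tr <- simulate_pbm(p, sim_config(dt, round(20 / dt), 51L, rec))
  r <- sqrt(rowSums(tr$pos^2))
  ratio <- (sum(r < 0.07) / 0.07^3) /
    (sum(r > 0.13 & r < 0.18) / (0.18^3 - 0.13^3))
  expect_equal(ratio, pbm_equilibrium_enhancement(p), tolerance = 0.10)
})

test_that("crowders are inert but slow down in-focus diffusion", {
  g <- geometry(0.1, 0.2)
  p <- pbm_params(g, Dn = 1, Db = 0.005, rho = 4.8e4, r_b = 0.01,
                  kappa = 100, k_off = 500)
  dt <- pbm_stable_dt(p, pb_max = 0.2)
  rec <- max(1L, round(2.5e-4 / dt)); dt2 <- 2.5e-4 / rec
  cfg <- sim_config(dt2, round(8 / dt2), 61L)
  cfg$record_every <- rec
  base <- init_binding_sites(p, cfg$seed)
  # count = 0 leaves the trajectory bit-identical
  tr0 <- simulate_pbm(p, cfg, sites = add_crowders(base, p, 0))
  tr0b <- simulate_pbm(p, cfg, sites = base)
  expect_identical(tr0$pos, tr0b$pos)
  # 400 extra inert spheres measurably reduce the in-focus diffusivity
  set.seed(62)
  tr1 <- simulate_pbm(p, cfg, sites = add_crowders(base, p, 400))
  Din <- function(tr) {
    r <- sqrt(rowSums(tr$pos^2)); n <- nrow(tr$pos)
    d2 <- rowSums((tr$pos[-1, ] - tr$pos[-n, ])^2)
    mean(d2[r[-n] < 0.06]) / (6 * 2.5e-4)
  }
  expect_lt(Din(tr1), Din(tr0))
})

test_that("slow exchange shows a near-zero displacement excess, fast does not", {
  g <- geometry(0.1, 0.5)
  mk <- function(k_off, rho, Tphys) {
    p <- pbm_params(g, Dn = 1, Db = 0.005, rho = rho, r_b = 0.01,
                    kappa = 100, k_off = k_off)
    dt <- pbm_stable_dt(p, pb_max = 0.2)
    # record densely (0.1 ms) so periodic unwrapping is safe, then thin
    cfg <- sim_config(dt, round(Tphys / dt), 71L, max(1L, round(1e-4 / dt)))
    as_track_table(unwrap_trajectory(
      simulate_pbm_bulk(p, cfg, box_size = 0.15)))[, 1:5]
  }
  thin <- function(tab, k) {
    out <- tab[seq(1, nrow(tab), by = k), ]
    out$frame <- seq_len(nrow(out)) - 1L
    out
  }
  # slow binding/unbinding relative to a 1 ms observation interval
  slow <- displacement_histogram(thin(mk(100, 2e3, 4), 10L), lag = 1L)
  expect_lt(slow$ks$p.value, 0.01)
  # fast exchange (k_off * dt_obs = 75): Gaussian displacements at matched
  # effective diffusivity
  fast <- displacement_histogram(thin(mk(5000, 4.8e4, 5), 150L), lag = 1L)
  expect_gt(fast$ks$p.value, 0.01)
})
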